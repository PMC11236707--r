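test_that("annotation generator honours p_antisense and the seed", {
  cfg <- sim_config(n_genes = 10, p_antisense = 1, seed = 11)
  tx <- simulate_annotation(cfg)
  expect_equal(sum(tx$biotype == "mRNA"), 10)
  expect_equal(sum(tx$biotype %in% c("XUT", "SUT", "CUT")), 10)
  # every asRNA pairs with its gene (generated fractions are >= 0.5)
  p <- find_pairs(tx)
  expect_equal(sort(p$sense_id), sort(tx$id[tx$biotype == "mRNA"]))

  cfg0 <- sim_config(n_genes = 10, p_antisense = 0, seed = 11)
  expect_true(all(simulate_annotation(cfg0)$biotype == "mRNA"))

  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
})

test_that("mRNA bodies never overlap and asRNAs stay clear of neighbours", {
  tx <- simulate_annotation(sim_config(n_genes = 80, seed = 3))
  m <- tx[tx$biotype == "mRNA", ]
  m <- m[order(m$start), ]
  expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  # each asRNA overlaps exactly one transcript: its own sense gene
  as_tx <- tx[tx$biotype != "mRNA", ]
  for (i in seq_len(nrow(as_tx))) {
    ov <- overlap_bp(as_tx[i, ],
                     data.frame(chrom = m$chrom, start = m$start, end = m$end))
    expect_equal(sum(ov > 0), 1)
  }
})

test_that("experiment generation is reproducible and truth is consistent", {
  cfg <- sim_config(n_genes = 60, seed = 5)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts$fractionation$counts,
                   s2$counts$fractionation$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$rnai, s2$rnai)
  # truth invariant: f_cyto is the logistic-linked function of pi_ds
  expect_equal(s1$truth$f_cyto,
               plogis(qlogis(cfg$base_cyto_fraction) +
                      cfg$coupling_strength * s1$truth$pi_ds))
  # pi_ds in [0,1], zero for unpaired transcripts
  expect_true(all(s1$truth$pi_ds >= 0 & s1$truth$pi_ds <= 1))
  unpaired <- setdiff(s1$truth$id, c(s1$pairs$sense_id, s1$pairs$antisense_id))
  expect_true(all(s1$truth$pi_ds[match(unpaired, s1$truth$id)] == 0))
})

test_that("zero coupling removes the propensity-localization link", {
  s <- simulate_experiment(sim_config(n_genes = 60, coupling_strength = 0,
                                      seed = 5))
  expect_equal(length(unique(s$truth$f_cyto)), 1L)
})

test_that("counts have negative-binomial spread, Poisson in the limit", {
  # fixed library sizes so the NB moments are uncontaminated
  cfg <- sim_config(n_genes = 400, p_antisense = 0, dispersion = 0.1,
                    library_size_range = c(1e6, 1e6), seed = 21)
  s <- simulate_experiment(cfg)
  K <- s$counts$fractionation$counts
  tot <- K[, s$counts$fractionation$samples$condition == "total", drop = FALSE]
  mu <- s$truth$mu
  v <- apply(tot, 1, var)
  expected <- mu + cfg$dispersion * mu^2
  # variance ratio pools to ~1 across genes (chi^2 noise at n=3 averages out)
  expect_equal(mean(v / expected), 1, tolerance = 0.15)

  cfg_p <- sim_config(n_genes = 400, p_antisense = 0, dispersion = 1e-6,
                      library_size_range = c(1e6, 1e6), seed = 22)
  sp <- simulate_experiment(cfg_p)
  Kp <- sp$counts$fractionation$counts
  totp <- Kp[, sp$counts$fractionation$samples$condition == "total",
             drop = FALSE]
  vp <- apply(totp, 1, var)
  expect_equal(mean(vp / sp$truth$mu), 1, tolerance = 0.15)
})

test_that("asRNA/mRNA expression ratio has the configured median", {
  cfg <- sim_config(n_genes = 500, p_antisense = 1, seed = 9)
  s <- simulate_experiment(cfg)
  tr <- s$truth
  r <- tr$mu[match(s$pairs$antisense_id, tr$id)] /
       tr$mu[match(s$pairs$sense_id, tr$id)]
  expect_equal(median(r), cfg$asrna_ratio_mean, tolerance = 0.2)
})

test_that("stress induction couples asRNAs to their induced mRNAs", {
  s <- simulate_experiment(sim_config(n_genes = 300, seed = 13))
  tr <- s$truth
  up <- tr$id[tr$biotype == "mRNA" & tr$stress_lfc > 0]
  as_ids <- paste0("as", up)
  lfc <- tr$stress_lfc[match(as_ids, tr$id)]
  lfc <- lfc[!is.na(lfc) & lfc != 0]
  expect_gt(mean(lfc > 0), 0.5)
})
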