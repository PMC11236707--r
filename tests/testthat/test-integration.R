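test_that("spearman handles monotone, reversed and tied inputs", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman(x, sort(x) [rank(x)]), 1)
  expect_equal(spearman(x, x^3), 1)          # monotone transform
  expect_equal(spearman(x, -x), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               spearman_oracle(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_warning(r <- spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(spearman(c(1, 2, NA), c(1, 2, 3)), "finite")
  set.seed(12)
  for (i in 1:50) {
    a <- rnorm(sample(3:100, 1)); b <- rnorm(length(a))
    expect_equal(spearman(a, b), spearman_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("distribution percentages partition each biotype to 100", {
  calls <- data.frame(
    id = sprintf("t%d", 1:6),
    call = factor(c("cytoplasmic", "nuclear", "not_significant",
                    "not_significant", "cytoplasmic", "cytoplasmic"),
                  levels = c("cytoplasmic", "nuclear", "not_significant")))
  bt <- c("mRNA", "mRNA", "mRNA", "mRNA", "asRNA", "asRNA")
  out <- distribution_percentages(calls, bt)
  m <- out[out$biotype == "mRNA", ]
  expect_equal(m$percent[match(c("cytoplasmic", "nuclear", "not_significant"),
                               m$call)], c(25, 25, 50))
  expect_equal(as.numeric(tapply(out$percent, out$biotype, sum)),
               c(100, 100), tolerance = 1e-9)
  all_cyto <- distribution_percentages(
    data.frame(id = "a", call = factor("cytoplasmic",
               levels = levels(calls$call))), "mRNA")
  expect_equal(all_cyto$percent[all_cyto$call == "cytoplasmic"], 100)
})

test_that("cytoplasmic share of enriched transcripts is a plain percentage", {
  j2 <- data.frame(id = sprintf("t%d", 1:8),
                   call = c(rep("cytoplasmic", 5), rep("not_significant", 3)))
  dist <- data.frame(id = sprintf("t%d", 1:8),
                     call = c(rep("cytoplasmic", 4), rep("nuclear", 4)))
  expect_equal(cytoplasmic_fraction_of_enriched(j2, dist), 80)
  none <- data.frame(id = sprintf("t%d", 1:8), call = "not_significant")
  expect_warning(r <- cytoplasmic_fraction_of_enriched(none, dist), "enriched")
  expect_true(is.na(r))
  disjoint <- data.frame(id = sprintf("u%d", 1:8), call = "cytoplasmic")
  expect_error(cytoplasmic_fraction_of_enriched(disjoint, dist), "share no")
})

test_that("asRNA-ratio bins hold means and route missing pairs aside", {
  lfc <- setNames(c(-1, -0.5, 0.2, 0.8, 1.5), sprintf("m%d", 1:5))
  ratio <- setNames(c(0.001, 0.05, 0.5, 2), sprintf("m%d", 2:5))
  out <- asrna_ratio_localization(ratio, lfc)
  expect_equal(out$bin, c("no_asRNA", "[0,0.01)", "[0.01,0.1)", "[0.1,1)",
                          "[1,Inf)"))
  expect_equal(out$n, rep(1L, 5))
  expect_equal(out$mean_log2fc, c(-1, -0.5, 0.2, 0.8, 1.5))
  # single populated bin when all ratios are tiny
  out2 <- asrna_ratio_localization(setNames(rep(1e-4, 5), names(lfc)), lfc)
  expect_equal(out2$bin, "[0,0.01)")
  expect_equal(out2$n, 5L)
  # no pairs at all: only the no_asRNA bin
  out3 <- asrna_ratio_localization(setNames(numeric(0), character(0)), lfc)
  expect_equal(out3$bin, "no_asRNA")
  expect_equal(out3$n, 5L)
})

test_that("stress asRNA up-fraction is computed over eligible mRNAs only", {
  mres <- data.frame(id = sprintf("m%d", 1:25),
                     padj = c(rep(0.01, 20), rep(0.5, 5)),
                     log2fc = 2, tested = TRUE)
  ares <- data.frame(id = sprintf("a%d", 1:25),
                     padj = 0.01,
                     log2fc = c(rep(1, 19), -1, rep(1, 5)), tested = TRUE)
  pairs <- data.frame(sense_id = sprintf("m%d", 1:25),
                      antisense_id = sprintf("a%d", 1:25))
  expect_equal(stress_asrna_fraction(mres, ares, pairs), 95)
  ares_down <- transform(ares, log2fc = -1)
  expect_equal(stress_asrna_fraction(mres, ares_down, pairs), 0)
  ares_ns <- transform(ares, padj = 0.9)
  expect_warning(r <- stress_asrna_fraction(mres, ares_ns, pairs), "no up")
  expect_true(is.na(r))
})

test_that("export-receptor footprint arithmetic matches the titration logic", {
  expect_equal(binding_footprint(36, 10, 2), 7L)
  expect_equal(binding_footprint(36, 5, 1), 7L)
  expect_equal(binding_footprint(50, 50, 1), 1L)
  expect_error(binding_footprint(36, 0, 2), "positive")
})
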