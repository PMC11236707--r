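#' Configuration for the synthetic yeast sense-antisense experiment
#'
#' Bundles every tunable of the generator with validated defaults. The
#' defaults describe a desk-scale yeast-like transcriptome: asRNAs expressed
#' around 10-fold below their mRNA, three biological replicates per
#' condition, NB-distributed counts, and a latent per-transcript duplex
#' propensity that couples to the cytoplasmic fraction.
#'
#' @param n_genes number of mRNAs.
#' @param p_antisense probability an mRNA carries an overlapping asRNA.
#' @param overlap_fraction_range range the asRNA's overlap fraction (of its
#'   own length) is drawn from.
#' @param mean_log_expression,sd_log_expression log-normal parameters for the
#'   true mRNA mean expression (natural log scale).
#' @param asrna_ratio_mean median asRNA/mRNA expression ratio (default 0.1,
#'   i.e. asRNAs ~10-fold lower).
#' @param dispersion NB dispersion alpha (variance `mu + alpha * mu^2`).
#' @param n_replicates biological replicates per condition.
#' @param coupling_strength delta (>= 0) linking duplex propensity to the
#'   cytoplasmic fraction on the logit scale.
#' @param base_cyto_fraction cytoplasmic fraction of a transcript with zero
#'   duplex propensity.
#' @param library_size_range per-sample library sizes are drawn uniformly
#'   from this range and converted to size factors relative to the mean.
#' @param seed integer seed; all draws flow from it.
#' @param p_stress_up fraction of mRNAs induced in the stress condition.
#' @param stress_lfc_mean mean log2 fold change of stress-induced mRNAs.
#' @param stress_coupling probability that the asRNA of an induced mRNA is
#'   co-induced (otherwise it is repressed).
#' @param rnai_coupling slope of log2(RNAi/WT) density on duplex propensity.
#' @param rnai_noise_sd Gaussian noise (log2 scale) on the RNAi/WT ratio.
#' @param dms_delta per-nucleotide DMS reactivity gain in dbp2-delta per unit
#'   duplex propensity.
#' @param dms_noise_sd per-nucleotide noise on the dbp2-delta reactivity.
#' @param chrom chromosome name of the single simulated chromosome.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 7)
sim_config <- function(n_genes = 500, p_antisense = 0.5,
                       overlap_fraction_range = c(0.5, 1),
                       mean_log_expression = log(200),
                       sd_log_expression = 1,
                       asrna_ratio_mean = 0.1, dispersion = 0.05,
                       n_replicates = 3, coupling_strength = 2,
                       base_cyto_fraction = 0.4,
                       library_size_range = c(8e5, 1.2e6), seed = 1,
                       p_stress_up = 0.2, stress_lfc_mean = 2,
                       stress_coupling = 0.95, rnai_coupling = 5,
                       rnai_noise_sd = 0.75, dms_delta = 0.3,
                       dms_noise_sd = 0.05, chrom = "chrSim") {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, p_antisense >= 0, p_antisense <= 1,
            length(overlap_fraction_range) == 2,
            overlap_fraction_range[1] > 0,
            overlap_fraction_range[1] <= overlap_fraction_range[2],
            overlap_fraction_range[2] <= 1,
            asrna_ratio_mean > 0, dispersion > 0, n_replicates >= 1,
            coupling_strength >= 0,
            base_cyto_fraction > 0, base_cyto_fraction < 1,
            length(library_size_range) == 2,
            library_size_range[1] > 0,
            library_size_range[1] <= library_size_range[2],
            p_stress_up >= 0, p_stress_up <= 1,
            stress_coupling >= 0, stress_coupling <= 1,
            dms_delta >= 0)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# run expr with a private RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a stranded yeast-like transcript annotation
#'
#' Places `n_genes` non-overlapping mRNAs on alternating strands of a single
#' linear chromosome. With probability `p_antisense` an mRNA receives an
#' opposite-strand asRNA anchored at the mRNA 3' end, its class drawn from
#' XUT/SUT/CUT with weights favouring XUT and its overlap fraction (of the
#' asRNA's own length) drawn from `overlap_fraction_range`. Inter-gene gaps
#' are sized so asRNA tails never reach the neighbouring gene. Deterministic
#' given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return A [transcript_table()]; asRNA ids are `"as<mRNA id>"`.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    glen <- round(runif(n, 500, 2000))
    has_as <- runif(n) < cfg$p_antisense
    as_len <- round(glen * runif(n, 0.6, 1))
    frac <- runif(n, cfg$overlap_fraction_range[1], cfg$overlap_fraction_range[2])
    ov <- pmin(pmax(1L, round(frac * as_len)), as_len, glen)
    tail_len <- ifelse(has_as, as_len - ov, 0)  # asRNA overhang past the gene
    strand <- rep(c("+", "-"), length.out = n)
    # a '+' gene's asRNA tail runs into the following gap; a '-' gene's runs
    # into the preceding one: size each gap for both of its neighbours
    tail_after <- ifelse(strand == "+", tail_len, 0) +
      c(ifelse(strand == "-", tail_len, 0)[-1], 0)
    gap <- round(runif(n, 200, 600)) + tail_after
    start <- cumsum(c(1000, glen[-n] + gap[-n]))
    end <- start + glen
    ids <- sprintf("YSIM%04d", seq_len(n))
    bt_as <- sample(c("XUT", "SUT", "CUT"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    # asRNA anchored at the mRNA 3' end, overhang running past it
    as_start <- ifelse(strand == "+", end - ov, start + ov - as_len)
    as_end <- as_start + as_len
    idx <- which(has_as)
    tx <- data.frame(
      id = c(ids, sprintf("as%s", ids[idx])),
      chrom = cfg$chrom,
      start = c(start, as_start[idx]),
      end = c(end, as_end[idx]),
      strand = c(strand, ifelse(strand[idx] == "+", "-", "+")),
      biotype = c(rep("mRNA", n), bt_as[idx]),
      stringsAsFactors = FALSE)
    if (any(tx$start < 0)) stop("infeasible geometry: negative coordinates")
    transcript_table(tx$id, tx$chrom, tx$start, tx$end, tx$strand, tx$biotype)
  })
}

#' Simulate the full multi-assay experiment with ground truth
#'
#' Draws true mean expression per transcript (log-normal; asRNA means scaled
#' by a log-normal ratio with median `asrna_ratio_mean`), assigns each
#' transcript a duplex propensity
#' `pi_ds = min(1, partner/own expression) * overlap_fraction` (0 when
#' unpaired) and a cytoplasmic fraction
#' `f_cyto = plogis(qlogis(base_cyto_fraction) + coupling_strength * pi_ds)`,
#' then generates:
#' \itemize{
#' \item fractionation counts: conditions `total` (weight 1) and `cytoplasm`
#'   (weight `f_cyto`), NB with the configured dispersion, `n_replicates`
#'   each, with per-sample library size factors;
#' \item J2 RIP counts: `J2_eluate` (weight `pi_ds`) vs `J2_unbound`
#'   (weight `1 - pi_ds`);
#' \item stress counts: `control` vs `stress`, where a random `p_stress_up`
#'   fraction of mRNAs is induced and their asRNAs are co-induced with
#'   probability `stress_coupling` (repressed otherwise);
#' \item RNAi/WT read densities with
#'   `log2(RNAi/WT) = rnai_coupling * pi_ds + noise`;
#' \item per-nucleotide DMS reactivities for wild type and dbp2-delta with
#'   `mut = wt + dms_delta * pi_ds + noise` (clamped at 0);
#' \item strand-specific per-base coverage with asRNA coverage concentrated
#'   over the sense-antisense overlap in proportion to `pi_ds`.
#' }
#'
#' @param cfg a [sim_config()].
#' @param annotation optional [transcript_table()] from
#'   [simulate_annotation()]; simulated from `cfg` when `NULL`.
#' @return A list with elements `annotation`, `pairs`, `truth` (data frame
#'   `id, biotype, mu, pi_ds, f_cyto, stress_lfc`), `counts` (named list of
#'   [count_matrix()] objects: `fractionation`, `j2`, `stress`), `rnai`
#'   (data frame `id, wt_density, rnai_density, log2_ratio`), `reactivity`
#'   (lists `wt` and `dbp2d` of per-nucleotide vectors) and `coverage`
#'   (a [coverage_track()]).
#' @export
simulate_experiment <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(cfg)
  validate_transcripts(annotation)
  pairs <- find_pairs(annotation, min_fraction = 1e-9)
  .with_seed(cfg$seed + 1L, {
    tx <- as.data.frame(annotation)
    n <- nrow(tx)
    len <- tx$end - tx$start
    is_mrna <- tx$biotype == "mRNA"

    mu <- numeric(n)
    mu[is_mrna] <- rlnorm(sum(is_mrna), cfg$mean_log_expression,
                          cfg$sd_log_expression)
    # asRNA expression: log-normal ratio with median asrna_ratio_mean
    sense_of <- sub("^as", "", tx$id)
    as_idx <- which(!is_mrna & sense_of %in% tx$id)
    ratio <- rlnorm(length(as_idx), log(cfg$asrna_ratio_mean), 0.5)
    mu[as_idx] <- mu[match(sense_of[as_idx], tx$id)] * ratio
    mu[mu == 0] <- rlnorm(sum(mu == 0), cfg$mean_log_expression - 3,
                          cfg$sd_log_expression)

    # duplex propensity: fraction of a transcript's molecules in duplex,
    # bounded by the partner/own molar ratio and the overlap extent
    pi_ds <- numeric(n)
    partner <- rep(NA_character_, n)
    m <- match(tx$id, pairs$sense_id)
    partner[!is.na(m)] <- pairs$antisense_id[m[!is.na(m)]]
    m <- match(tx$id, pairs$antisense_id)
    partner[!is.na(m)] <- pairs$sense_id[m[!is.na(m)]]
    ovf <- setNames(rep(NA_real_, n), tx$id)
    ovf[pairs$antisense_id] <- pairs$overlap_bp /
      (len[match(pairs$antisense_id, tx$id)])
    ovf[pairs$sense_id] <- pairs$overlap_bp / len[match(pairs$sense_id, tx$id)]
    paired <- !is.na(partner)
    pidx <- match(partner[paired], tx$id)
    pi_ds[paired] <- pmin(1, mu[pidx] / mu[paired]) * ovf[tx$id[paired]]
    f_cyto <- plogis(qlogis(cfg$base_cyto_fraction) +
                     cfg$coupling_strength * pi_ds)

    nr <- cfg$n_replicates
    lib_factor <- function(k) {
      ls <- runif(k, cfg$library_size_range[1], cfg$library_size_range[2])
      ls / mean(cfg$library_size_range)
    }
    nb_draw <- function(w_mat, sf) {
      K <- matrix(0L, n, length(sf))
      for (j in seq_along(sf)) {
        mu_j <- mu * w_mat[, ceiling(j / nr)] * sf[j]
        K[, j] <- rnbinom(n, mu = mu_j, size = 1 / cfg$dispersion)
      }
      rownames(K) <- tx$id
      K
    }
    make_cm <- function(assay, conds, w_mat) {
      sf <- lib_factor(2 * nr)
      K <- nb_draw(w_mat, sf)
      samples <- data.frame(
        sample = paste(rep(conds, each = nr), rep(seq_len(nr), 2), sep = "_"),
        assay = assay,
        condition = rep(conds, each = nr),
        replicate = rep(seq_len(nr), 2), stringsAsFactors = FALSE)
      colnames(K) <- samples$sample
      count_matrix(K, samples)
    }

    frac_cm <- make_cm("fractionation", c("total", "cytoplasm"),
                       cbind(1, f_cyto))
    j2_cm <- make_cm("j2", c("J2_eluate", "J2_unbound"),
                     cbind(pi_ds, 1 - pi_ds))

    stress_lfc <- numeric(n)
    up <- which(is_mrna & runif(n) < cfg$p_stress_up)
    stress_lfc[up] <- rnorm(length(up), cfg$stress_lfc_mean, 0.5)
    as_of_up <- match(paste0("as", tx$id[up]), tx$id)
    hit <- !is.na(as_of_up)
    co <- runif(sum(hit)) < cfg$stress_coupling
    as_hit <- as_of_up[hit]
    stress_lfc[as_hit[co]] <- rnorm(sum(co), cfg$stress_lfc_mean, 0.5)
    stress_lfc[as_hit[!co]] <- rnorm(sum(!co), -cfg$stress_lfc_mean, 0.5)
    stress_cm <- make_cm("stress", c("control", "stress"),
                         cbind(1, 2 ^ stress_lfc))

    rnai <- data.frame(
      id = tx$id,
      wt_density = mu / len * 1e3,
      stringsAsFactors = FALSE)
    rnai$log2_ratio <- cfg$rnai_coupling * pi_ds + rnorm(n, 0, cfg$rnai_noise_sd)
    rnai$rnai_density <- rnai$wt_density * 2 ^ rnai$log2_ratio
    rnai <- rnai[, c("id", "wt_density", "rnai_density", "log2_ratio")]

    wt_react <- lapply(seq_len(n), function(i) rgamma(len[i], shape = 1, rate = 2))
    names(wt_react) <- tx$id
    mut_react <- lapply(seq_len(n), function(i)
      pmax(0, wt_react[[i]] + cfg$dms_delta * pi_ds[i] +
                rnorm(len[i], 0, cfg$dms_noise_sd)))
    names(mut_react) <- tx$id

    chrom_len <- max(tx$end) + 1000L
    cov <- list("+" = setNames(list(numeric(chrom_len)), cfg$chrom),
                "-" = setNames(list(numeric(chrom_len)), cfg$chrom))
    for (i in seq_len(n)) {
      s <- tx$strand[i]
      body <- (tx$start[i] + 1L):tx$end[i]
      cov[[s]][[cfg$chrom]][body] <- cov[[s]][[cfg$chrom]][body] + mu[i] / 10
    }
    # duplex-dependent extra coverage over the overlap region (degradation
    # products concentrate where the duplex forms)
    for (k in seq_len(nrow(pairs))) {
      a <- match(pairs$antisense_id[k], tx$id)
      s_i <- match(pairs$sense_id[k], tx$id)
      lo <- max(tx$start[a], tx$start[s_i]) + 1L
      hi <- min(tx$end[a], tx$end[s_i])
      if (hi < lo) next
      st <- tx$strand[a]
      cov[[st]][[cfg$chrom]][lo:hi] <-
        cov[[st]][[cfg$chrom]][lo:hi] + pi_ds[a] * mu[a] / 5
    }
    cov <- coverage_track(cov)

    truth <- data.frame(id = tx$id, biotype = tx$biotype, mu = mu,
                        pi_ds = pi_ds, f_cyto = f_cyto,
                        stress_lfc = stress_lfc, stringsAsFactors = FALSE)

    list(annotation = annotation, pairs = pairs, truth = truth,
         counts = list(fractionation = frac_cm, j2 = j2_cm,
                       stress = stress_cm),
         rnai = rnai,
         reactivity = list(wt = wt_react, dbp2d = mut_react),
         coverage = cov)
  })
}

#' Simulate an smFISH region-measurement table with known partitioning
#'
#' Emits one `total_cell` and one `nucleus` row per cell with integrated
#' densities consistent with a drawn nuclear fraction, plus uniform
#' background, so the nuclear/cytoplasmic arithmetic can be checked against
#' ground truth.
#'
#' @param n_cells number of cells.
#' @param mean_signal mean true total signal per cell.
#' @param nuclear_fraction_range range the per-cell nuclear fraction is
#'   drawn from.
#' @param background_mean mean per-pixel background fluorescence.
#' @param seed integer seed.
#' @return A list: `measurements` (data frame `cell, region,
#'   integrated_density, area, bg1, bg2, bg3`) and `truth` (data frame
#'   `cell, total_signal, nuclear_signal`).
#' @export
simulate_smfish_table <- function(n_cells = 50, mean_signal = 5000,
                                  nuclear_fraction_range = c(0.2, 0.8),
                                  background_mean = 2, seed = 1) {
  .with_seed(seed, {
    total <- rlnorm(n_cells, log(mean_signal), 0.3)
    nf <- runif(n_cells, nuclear_fraction_range[1], nuclear_fraction_range[2])
    nuc <- total * nf
    area_tot <- round(runif(n_cells, 300, 600))
    area_nuc <- round(area_tot * runif(n_cells, 0.2, 0.4))
    bg <- matrix(rgamma(3 * n_cells, shape = 4, rate = 4 / background_mean),
                 n_cells, 3)
    bg_mean <- rowMeans(bg)
    meas <- data.frame(
      cell = rep(sprintf("cell%03d", seq_len(n_cells)), each = 2),
      region = rep(c("total_cell", "nucleus"), n_cells),
      integrated_density = as.vector(rbind(total + area_tot * bg_mean,
                                           nuc + area_nuc * bg_mean)),
      area = as.vector(rbind(area_tot, area_nuc)),
      bg1 = rep(bg[, 1], each = 2), bg2 = rep(bg[, 2], each = 2),
      bg3 = rep(bg[, 3], each = 2), stringsAsFactors = FALSE)
    list(measurements = meas,
         truth = data.frame(cell = sprintf("cell%03d", seq_len(n_cells)),
                            total_signal = total, nuclear_signal = nuc,
                            stringsAsFactors = FALSE))
  })
}
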