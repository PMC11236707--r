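#' Bundle a count matrix with its sample sheet
#'
#' @param counts transcripts x samples matrix of non-negative integer counts
#'   with row names (transcript ids) and column names (sample ids).
#' @param samples data frame with columns `sample`, `assay`, `condition`
#'   (one of `total, cytoplasm, J2_eluate, J2_unbound, RNAi, WT, stress,
#'   control`) and `replicate`; rows match `colnames(counts)`.
#' @return A list of class `count_matrix` with elements `counts`, `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry transcript row names")
  if (any(counts < 0)) stop("negative counts are not allowed")
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (!identical(colnames(counts), as.character(samples$sample)))
    stop("sample sheet rows must match count matrix columns (in order)")
  out <- list(counts = counts, samples = as.data.frame(samples))
  class(out) <- "count_matrix"
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " transcripts x ", ncol(x$counts),
      " samples\n", sep = "")
  print(table(x$samples$condition))
  invisible(x)
}

#' Drop low-count transcripts
#'
#' Retains transcripts whose mean raw count across all samples of the matrix
#' is strictly greater than `threshold` (default 40); row order is
#' preserved. Applied per contrast before testing, mirroring the convention
#' of considering only transcripts with an average count above 40.
#'
#' @param cm a [count_matrix()] (or bare matrix).
#' @param threshold mean-count threshold; strict `>` comparison.
#' @return Filtered object of the same type.
#' @export
filter_low_counts <- function(cm, threshold = 40) {
  if (inherits(cm, "count_matrix")) {
    keep <- rowMeans(cm$counts) > threshold
    cm$counts <- cm$counts[keep, , drop = FALSE]
    return(cm)
  }
  cm[rowMeans(cm) > threshold, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference
#' transcripts (rows with a positive count in every sample) of the ratio of
#' the sample's count to the row geometric mean; factors are rescaled so
#' their geometric mean is 1.
#'
#' @param cm a [count_matrix()] or bare count matrix.
#' @return Numeric vector of per-sample size factors (geometric mean 1).
#' @export
estimate_size_factors <- function(cm) {
  K <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  ref <- rowSums(K > 0) == ncol(K)
  if (!any(ref))
    stop("no transcript has positive counts in every sample; ",
         "cannot compute median-of-ratios size factors - supply deeper ",
         "counts or filter samples")
  logK <- log(K[ref, , drop = FALSE])
  log_geo <- rowMeans(logK)
  sf <- exp(apply(logK - log_geo, 2, median))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(K))
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up FDR adjustment of the non-missing p values (via
#' [stats::p.adjust()]); `NA`/`NaN` entries are propagated unchanged so
#' untested transcripts stay untested.
#'
#' @param p numeric vector of p values in `[0, 1]` (NAs allowed).
#' @return Adjusted p values, capped at 1, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Log2 ratio with a conditional pseudocount
#'
#' Computes `log2(num / den)`; when either input is zero (or with
#' `mode = "always"`), the pseudocount is added to both numerator and
#' denominator to keep the ratio finite.
#'
#' @param num,den non-negative numerics (vectorised).
#' @param pseudocount value added to both terms when triggered (default 1).
#' @param mode `"if_zero"` (default: apply only where either input is 0),
#'   `"always"`, or `"never"`.
#' @return `log2((num + c) / (den + c))` with `c` as per `mode`.
#' @export
#' @examples
#' log2_ratio(8, 2, mode = "never")       # 2
#' log2_ratio(0, 4)                       # log2(1/5)
log2_ratio <- function(num, den, pseudocount = 1,
                       mode = c("if_zero", "always", "never")) {
  mode <- match.arg(mode)
  stopifnot(all(num >= 0), all(den >= 0), pseudocount >= 0)
  c_vec <- switch(mode,
    if_zero = ifelse(num == 0 | den == 0, pseudocount, 0),
    always  = rep(pseudocount, length(num)),
    never   = rep(0, length(num)))
  if (any((num + c_vec) == 0 & (den + c_vec) == 0))
    stop("log2 ratio undefined: numerator and denominator both zero ",
         "with no pseudocount")
  log2((num + c_vec) / (den + c_vec))
}

# gene-wise NB dispersion by method of moments on normalized counts,
# pooled within condition; negative estimates floor to the Poisson limit
.mom_dispersion <- function(N1, N2) {
  n1 <- ncol(N1); n2 <- ncol(N2)
  m1 <- rowMeans(N1); m2 <- rowMeans(N2)
  v1 <- if (n1 > 1) apply(N1, 1, var) else rep(0, nrow(N1))
  v2 <- if (n2 > 1) apply(N2, 1, var) else rep(0, nrow(N2))
  num <- (n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  a <- ifelse(den > 0, num / den, 0)
  pmax(a, 0)
}

#' Negative-binomial Wald test for a two-condition contrast
#'
#' Minimal NB differential-abundance test: counts are normalized by
#' median-of-ratios size factors, per-condition means are fitted, gene-wise
#' dispersions are estimated by method of moments and (by default) moderated
#' toward the across-gene mean dispersion with prior weight `prior_df`
#' (replicate-level moment estimates are far too noisy at n = 3 for a
#' normal-reference Wald statistic; moderation restores calibration). The
#' log2 fold change is `log2(mean_num / mean_den)`, its standard error comes
#' from the NB Fisher information
#' (`Var(log mu_hat) ~ (1/mu + alpha) / n` per condition, delta method), and
#' the two-sided p value from the standard normal. No fold-change shrinkage
#' or independent filtering is performed.
#'
#' If a condition's fitted mean is exactly zero, a pseudo-mean of 0.5
#' normalized counts is added to that condition only and the transcript is
#' flagged in the `zero_guard` column.
#'
#' @param cm a [count_matrix()].
#' @param contrast character pair `c(numerator, denominator)` naming
#'   conditions in the sample sheet.
#' @param size_factors optional per-sample size factors for the contrast's
#'   samples; estimated by [estimate_size_factors()] when `NULL`.
#' @param dispersion `"moderated"` (default), `"gene"` (raw gene-wise
#'   moments) or `"common"` (one pooled value for all genes).
#' @param prior_df prior weight of the common dispersion under
#'   `"moderated"`.
#' @param dispersion_floor lower bound on the dispersion (default 1e-8).
#' @return An `enrichment_result` data frame with columns `id, base_mean,
#'   log2fc, se, wald_stat, p, padj, zero_guard, tested`, plus attributes
#'   `contrast` and `size_factors`. Rows keep the input order.
#' @export
nb_wald_test <- function(cm, contrast, size_factors = NULL,
                         dispersion = c("moderated", "gene", "common"),
                         prior_df = 10, dispersion_floor = 1e-8) {
  dispersion <- match.arg(dispersion)
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  cond <- cm$samples$condition
  j1 <- which(cond == contrast[1])
  j2 <- which(cond == contrast[2])
  if (!length(j1) || !length(j2))
    stop("contrast condition(s) absent from sample sheet: ",
         paste(setdiff(contrast, cond), collapse = ", "))
  if (length(j1) + length(j2) < 3)
    stop("need at least 3 samples across the two conditions")
  K <- cm$counts[, c(j1, j2), drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(K)
  N <- sweep(K, 2, size_factors, "/")
  n1 <- length(j1); n2 <- length(j2)
  N1 <- N[, seq_len(n1), drop = FALSE]
  N2 <- N[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(N1); m2 <- rowMeans(N2)

  a_g <- .mom_dispersion(N1, N2)
  a_use <- switch(dispersion,
    gene = a_g,
    common = rep(mean(a_g), length(a_g)),
    moderated = {
      df <- n1 + n2 - 2
      (prior_df * mean(a_g) + df * a_g) / (prior_df + df)
    })
  a_use <- pmax(a_use, dispersion_floor)

  zero_guard <- m1 == 0 | m2 == 0
  m1g <- ifelse(m1 == 0, 0.5, m1)
  m2g <- ifelse(m2 == 0, 0.5, m2)
  log2fc <- log2(m1g / m2g)
  se <- sqrt((1 / m1g + a_use) / n1 + (1 / m2g + a_use) / n2) / log(2)
  wald <- log2fc / se
  p <- 2 * pnorm(-abs(wald))
  res <- data.frame(id = rownames(K), base_mean = rowMeans(N),
                    log2fc = log2fc, se = se, wald_stat = wald, p = p,
                    padj = bh_adjust(p), zero_guard = zero_guard,
                    tested = TRUE, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  attr(res, "size_factors") <- size_factors
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Filter, normalize and test a contrast in one call
#'
#' Convenience wrapper: applies the low-count filter to the contrast's
#' samples, estimates size factors, runs [nb_wald_test()] and reports every
#' input transcript, with filtered-out transcripts marked `tested = FALSE`
#' and `NA` statistics.
#'
#' @inheritParams nb_wald_test
#' @param count_threshold mean-count filter threshold (strict `>`,
#'   default 40).
#' @param ... passed to [nb_wald_test()].
#' @return An `enrichment_result` covering all input transcripts.
#' @export
enrichment_test <- function(cm, contrast, count_threshold = 40, ...) {
  stopifnot(inherits(cm, "count_matrix"))
  keep_samples <- cm$samples$condition %in% contrast
  sub <- count_matrix(cm$counts[, keep_samples, drop = FALSE],
                      cm$samples[keep_samples, , drop = FALSE])
  filt <- filter_low_counts(sub, count_threshold)
  res <- nb_wald_test(filt, contrast, ...)
  out <- data.frame(id = rownames(cm$counts),
                    base_mean = NA_real_, log2fc = NA_real_, se = NA_real_,
                    wald_stat = NA_real_, p = NA_real_, padj = NA_real_,
                    zero_guard = FALSE, tested = FALSE,
                    stringsAsFactors = FALSE)
  m <- match(res$id, out$id)
  out[m, names(res)] <- res
  attr(out, "contrast") <- contrast
  attr(out, "size_factors") <- attr(res, "size_factors")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("NB Wald enrichment test: ", ct[1], " vs ", ct[2], "\n", sep = "")
  cat(sum(x$tested), " of ", nrow(x), " transcripts tested\n", sep = "")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, alpha = 0.05, ...) {
  tested <- object[object$tested, , drop = FALSE]
  sig <- tested$padj < alpha
  out <- list(contrast = attr(object, "contrast"), n = nrow(object),
              n_tested = nrow(tested),
              n_up = sum(sig & tested$log2fc > 0, na.rm = TRUE),
              n_down = sum(sig & tested$log2fc < 0, na.rm = TRUE),
              alpha = alpha)
  class(out) <- "summary.enrichment_result"
  out
}

#' @export
print.summary.enrichment_result <- function(x, ...) {
  cat("Contrast ", x$contrast[1], " vs ", x$contrast[2], ": ",
      x$n_tested, "/", x$n, " tested; at padj < ", x$alpha, ": ",
      x$n_up, " up, ", x$n_down, " down\n", sep = "")
  invisible(x)
}

#' MA-style plot of an enrichment result
#'
#' @param x an `enrichment_result`.
#' @param alpha significance threshold used for colouring.
#' @param ... passed to [graphics::plot()].
#' @export
plot.enrichment_result <- function(x, alpha = 0.05, ...) {
  t <- x[x$tested, , drop = FALSE]
  sig <- !is.na(t$padj) & t$padj < alpha
  graphics::plot(log10(t$base_mean), t$log2fc,
                 col = ifelse(sig, "firebrick", "grey50"), pch = 20,
                 xlab = "log10 base mean", ylab = "log2 fold change", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
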