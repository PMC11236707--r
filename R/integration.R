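#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), via
#' [stats::cor()]. A constant input has no defined rank correlation and
#' yields `NA` with a warning.
#'
#' @param x,y equal-length numeric vectors (length >= 3, finite).
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("spearman requires finite inputs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Distribution-class percentages by biotype
#'
#' For each biotype, the percentage of transcripts in each distribution
#' class (e.g. cytoplasmic / nuclear / not significant). Percentages within
#' a biotype sum to 100.
#'
#' @param calls data frame from [classify_distribution()].
#' @param biotypes character vector of biotypes aligned with `calls` rows.
#' @return Data frame `biotype, call, n, percent`; empty biotypes omitted.
#' @export
#' @examples
#' # 4 mRNAs called (cyt, nuc, NS, NS) -> 25 / 25 / 50
distribution_percentages <- function(calls, biotypes) {
  stopifnot(nrow(calls) == length(biotypes))
  out <- list()
  for (bt in unique(biotypes)) {
    cc <- calls$call[biotypes == bt]
    tab <- table(cc)
    out[[bt]] <- data.frame(biotype = bt, call = names(tab),
                            n = as.integer(tab),
                            percent = 100 * as.integer(tab) / length(cc),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentage of enriched transcripts that are cytoplasmic
#'
#' Among transcripts called enriched in one contrast (e.g. the J2
#' eluate-vs-unbound RIP), the percentage called cytoplasmic in the
#' fractionation contrast.
#'
#' @param j2_calls,distribution_calls data frames from
#'   [classify_distribution()]; must share their id universe.
#' @param enriched_label label marking enrichment in `j2_calls` (default
#'   `"cytoplasmic"`, the generic enriched class).
#' @param cyto_label label marking cytoplasmic in `distribution_calls`.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when nothing
#'   is enriched.
#' @export
cytoplasmic_fraction_of_enriched <- function(j2_calls, distribution_calls,
                                             enriched_label = "cytoplasmic",
                                             cyto_label = "cytoplasmic") {
  if (!any(j2_calls$id %in% distribution_calls$id))
    stop("call sets share no transcript ids")
  enr <- j2_calls$id[j2_calls$call == enriched_label]
  if (!length(enr)) {
    warning("no enriched transcripts; percentage undefined")
    return(NA_real_)
  }
  m <- match(enr, distribution_calls$id)
  if (anyNA(m)) stop("enriched transcripts missing from distribution calls")
  100 * mean(distribution_calls$call[m] == cyto_label)
}

#' Mean mRNA nucleo-cytoplasmic distribution by relative asRNA expression
#'
#' Bins mRNAs by their asRNA:mRNA expression ratio (decade bins by default,
#' with ratio >= 1 meaning the asRNA is present in equal or higher amounts)
#' and reports the mean cytoplasm:total log2 fold change per bin. mRNAs
#' without an asRNA go to a dedicated `no_asRNA` bin.
#'
#' @param ratio named numeric vector of asRNA/mRNA expression ratios (names
#'   are mRNA ids); mRNAs absent from it count as having no asRNA.
#' @param log2fc named numeric vector of mRNA cytoplasm:total log2 fold
#'   changes (names are mRNA ids).
#' @param ratio_bins bin edges (default `c(0, 0.01, 0.1, 1, Inf)`).
#' @return Data frame `bin, n, mean_log2fc`, ordered `no_asRNA` then
#'   ascending ratio bins.
#' @export
asrna_ratio_localization <- function(ratio, log2fc,
                                     ratio_bins = c(0, 0.01, 0.1, 1, Inf)) {
  ids <- names(log2fc)
  stopifnot(!is.null(ids))
  r <- ratio[ids]
  lab <- paste0("[", utils::head(ratio_bins, -1), ",",
                utils::tail(ratio_bins, -1), ")")
  bin <- rep("no_asRNA", length(ids))
  has <- !is.na(r)
  bin[has] <- lab[findInterval(r[has], ratio_bins,
                               rightmost.closed = FALSE)]
  lv <- c("no_asRNA", lab)
  bin <- factor(bin, levels = lv)
  keep <- levels(bin)[table(bin) > 0]
  data.frame(bin = keep,
             n = as.integer(table(bin)[keep]),
             mean_log2fc = as.numeric(tapply(log2fc, bin, mean)[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of up-regulated mRNAs whose asRNA is also up
#'
#' Among mRNAs significantly increased in a stress-vs-control contrast whose
#' paired asRNA is significantly changed in the same contrast, the
#' percentage whose asRNA log2 fold change is positive.
#'
#' @param mrna_res,asrna_res `enrichment_result` objects for the
#'   stress:control contrast restricted to mRNAs and asRNAs respectively
#'   (they may be the same object covering both).
#' @param pairs pair table from [find_pairs()].
#' @param alpha significance threshold on `padj` (default 0.05).
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when no mRNA
#'   qualifies.
#' @export
stress_asrna_fraction <- function(mrna_res, asrna_res, pairs, alpha = 0.05) {
  up <- mrna_res$id[mrna_res$tested & !is.na(mrna_res$padj) &
                    mrna_res$padj < alpha & mrna_res$log2fc > 0]
  p <- pairs[pairs$sense_id %in% up, , drop = FALSE]
  m <- match(p$antisense_id, asrna_res$id)
  ok <- !is.na(m) & asrna_res$tested[m] & !is.na(asrna_res$padj[m]) &
        asrna_res$padj[m] < alpha
  if (!any(ok)) {
    warning("no up-regulated mRNA has a significantly changed asRNA")
    return(NA_real_)
  }
  100 * mean(asrna_res$log2fc[m[ok]] > 0)
}

#' Export-receptor footprint on an RNA substrate
#'
#' Window length (in bp or nt) accommodating `units_per_window` bound
#' receptor heterodimers at binding saturation, inferred from titration:
#' a substrate of `substrate_len` saturated at `saturation_excess`-fold
#' molar excess binds one unit per `substrate_len / saturation_excess`
#' bases, so `units_per_window` units occupy
#' `floor(units_per_window * substrate_len / saturation_excess)` bases.
#'
#' @param substrate_len substrate length in nt/bp (> 0).
#' @param saturation_excess molar excess at binding saturation (> 0).
#' @param units_per_window heterodimers per reported window (> 0).
#' @return Integer window length.
#' @export
#' @examples
#' binding_footprint(36, 10, 2)  # dsRNA: two heterodimers every 7 bp
#' binding_footprint(36, 5, 1)   # ssRNA: one heterodimer every 7 nt
binding_footprint <- function(substrate_len, saturation_excess,
                              units_per_window) {
  if (substrate_len <= 0 || saturation_excess <= 0 || units_per_window <= 0)
    stop("all binding_footprint inputs must be positive")
  as.integer(floor(units_per_window * substrate_len / saturation_excess))
}
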