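#' Nucleo-cytoplasmic (or J2 enrichment) distribution calls
#'
#' Turns a tested contrast into the three-way call used for fractionation
#' RNA-seq (cytoplasm vs total) and J2 RIP-seq (eluate vs unbound):
#' `cytoplasmic` (equivalently, enriched) when `padj < alpha` and
#' `log2fc > lfc_min`, `nuclear` (depleted) when `padj < alpha` and
#' `log2fc < -lfc_min`, otherwise `not_significant`. Untested transcripts
#' are `not_significant` with `flag_untested = TRUE`.
#'
#' @param res an `enrichment_result` (see [nb_wald_test()]).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 0; no
#'   fold-change cut-off beyond significance).
#' @param labels length-2 character: labels for the enriched and depleted
#'   classes (default `c("cytoplasmic", "nuclear")`).
#' @return Data frame `id, call, padj, log2fc, flag_untested`; `call` is a
#'   factor with levels enriched/depleted/`not_significant`.
#' @export
classify_distribution <- function(res, alpha = 0.05, lfc_min = 0,
                                  labels = c("cytoplasmic", "nuclear")) {
  stopifnot(length(labels) == 2, alpha > 0, alpha <= 1, lfc_min >= 0)
  lv <- c(labels, "not_significant")
  call <- rep("not_significant", nrow(res))
  ok <- res$tested & !is.na(res$padj)
  call[ok & res$padj < alpha & res$log2fc > lfc_min] <- labels[1]
  call[ok & res$padj < alpha & res$log2fc < -lfc_min] <- labels[2]
  data.frame(id = res$id, call = factor(call, levels = lv),
             padj = res$padj, log2fc = res$log2fc,
             flag_untested = !res$tested, stringsAsFactors = FALSE)
}

#' dsRNA-propensity group from a log2 RNAi/WT ratio
#'
#' Bins the log2-transformed RNAi/wild-type density ratio into ten groups
#' labelled -5..-1 and 1..5 (no 0). On the positive side group k covers
#' `[k-1, k)` for k = 1..4 and group 5 covers ratios of 4 and above; the
#' negative side mirrors this. A ratio of exactly 0 falls in group 1 (the
#' half-open convention; only labels skip 0, not values).
#'
#' @param log2fc finite numeric vector of log2(RNAi/WT) ratios.
#' @return Integer vector of group labels in `{-5..-1, 1..5}`.
#' @export
#' @examples
#' propensity_group(c(0.5, 4.5, -1.5, 0))  # 1, 5, -2, 1
propensity_group <- function(log2fc) {
  if (any(!is.finite(log2fc)))
    stop("propensity_group requires finite log2 ratios")
  pos <- pmin(floor(log2fc) + 1, 5)
  neg <- -pmin(floor(-log2fc) + 1, 5)
  as.integer(ifelse(log2fc >= 0, pos, neg))
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param count read count (vectorised).
#' @param length_bp transcript length in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return `count * 1e9 / (length_bp * library_size)`.
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0) || any(library_size <= 0))
    stop("length_bp and library_size must be positive")
  count * 1e9 / (length_bp * library_size)
}

#' Select ssRNA/dsRNA validation targets from three evidence layers
#'
#' A sense/antisense pair is a `dsRNA_target` when the asRNA out-expresses
#' the mRNA (RPKM), the RNAi-seq propensity group is positive, and the pair
#' is J2-enriched. It is an `ssRNA_target` when the asRNA is below 1:100 of
#' the mRNA, the propensity group is negative, and it is not J2-enriched.
#' Everything else (including any pair with a missing evidence layer, which
#' is flagged) is `neither`.
#'
#' @param sense_rpkm,asrna_rpkm RPKM of the mRNA and its asRNA.
#' @param rnai_group propensity group from [propensity_group()].
#' @param j2_enriched logical: J2 eluate-vs-unbound call is enriched.
#' @return Data frame `label` (factor `dsRNA_target/ssRNA_target/neither`)
#'   and `flag_missing`.
#' @export
select_export_targets <- function(sense_rpkm, asrna_rpkm, rnai_group,
                                  j2_enriched) {
  n <- length(sense_rpkm)
  miss <- is.na(sense_rpkm) | is.na(asrna_rpkm) | is.na(rnai_group) |
          is.na(j2_enriched)
  label <- rep("neither", n)
  ds <- !miss & asrna_rpkm > sense_rpkm & rnai_group >= 1 & j2_enriched
  ss <- !miss & asrna_rpkm < sense_rpkm / 100 & rnai_group <= -1 & !j2_enriched
  label[ds] <- "dsRNA_target"
  label[ss] <- "ssRNA_target"
  data.frame(label = factor(label,
                            levels = c("dsRNA_target", "ssRNA_target",
                                       "neither")),
             flag_missing = miss)
}
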