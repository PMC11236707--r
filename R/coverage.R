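#' Strand-specific per-base coverage container
#'
#' A coverage track holds per-base read depth as numeric vectors indexed by
#' strand and chromosome; position i of a vector is depth at 0-based
#' position i - 1.
#'
#' @param depths a list `list("+" = list(chrom = numeric...), "-" = ...)`.
#' @return The validated list with class `coverage_track`.
#' @export
coverage_track <- function(depths) {
  stopifnot(is.list(depths), all(names(depths) %in% c("+", "-")))
  for (s in names(depths))
    for (ch in names(depths[[s]]))
      if (any(depths[[s]][[ch]] < 0)) stop("negative depth in track")
  class(depths) <- "coverage_track"
  depths
}

#' Read strand-specific bedGraph files into a coverage track
#'
#' bedGraph intervals are 0-based half-open; parsing goes through
#' `rtracklayer`. Chromosome lengths default to the furthest covered
#' position per chromosome.
#'
#' @param plus_file,minus_file bedGraph paths for the two strands; either
#'   may be `NULL`.
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return A [coverage_track()].
#' @export
read_bedgraph_track <- function(plus_file = NULL, minus_file = NULL,
                                chrom_lengths = NULL) {
  read_one <- function(path) {
    if (is.null(path)) return(list())
    gr <- rtracklayer::import(path, format = "bedGraph")
    out <- list()
    for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
        chrom_lengths[[ch]] else max(GenomicRanges::end(g))
      v <- numeric(len)
      for (k in seq_along(g)) {
        v[GenomicRanges::start(g)[k]:GenomicRanges::end(g)[k]] <-
          S4Vectors::mcols(g)$score[k]
      }
      out[[ch]] <- v
    }
    out
  }
  coverage_track(list("+" = read_one(plus_file), "-" = read_one(minus_file)))
}

#' Write one strand of a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param strand `"+"` or `"-"`.
#' @param path destination bedGraph file.
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(track, strand, path) {
  stopifnot(inherits(track, "coverage_track"), strand %in% names(track))
  rows <- list()
  for (ch in names(track[[strand]])) {
    v <- track[[strand]][[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      rows[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                               end = ends[keep], score = r$values[keep])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               score = numeric())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Percentile-binned gene-body coverage profile
#'
#' Splits the transcript body into `n_bins` equal-width bins ordered 5' to
#' 3' in transcript orientation (bins are reversed for minus-strand
#' transcripts) and averages the per-base depth within each bin. For
#' transcripts shorter than `n_bins` a representative base is sampled per
#' bin, so bases may repeat.
#'
#' @param track a [coverage_track()].
#' @param transcript one row of a [transcript_table()] (data frame or list
#'   with `chrom, start, end, strand`).
#' @param n_bins number of bins (default 100).
#' @return Numeric vector of length `n_bins` of mean depths.
#' @export
gene_body_profile <- function(track, transcript, n_bins = 100) {
  stopifnot(inherits(track, "coverage_track"))
  s <- transcript$strand
  ch <- transcript$chrom
  if (!(s %in% names(track)) || !(ch %in% names(track[[s]])))
    stop("track has no coverage for ", ch, " (", s, ")")
  v <- track[[s]][[ch]]
  if (transcript$end > length(v)) stop("transcript extends beyond track")
  depth <- v[(transcript$start + 1):transcript$end]
  L <- length(depth)
  if (L >= n_bins) {
    bin <- floor((seq_len(L) - 1) * n_bins / L) + 1
    prof <- as.numeric(tapply(depth, bin, mean))
  } else {
    prof <- depth[floor((seq_len(n_bins) - 0.5) * L / n_bins) + 1]
  }
  if (s == "-") prof <- rev(prof)
  prof
}

#' Aggregate gene-body profiles by transcript class
#'
#' Computes the bin-wise mean profile per biotype over the supplied
#' transcripts. Before aggregation, transcripts overlapping another
#' transcript of the aggregated classes on the same strand are excluded
#' (both members), mirroring the exclusion applied to class-filtered
#' coverage input; set `exclude_same_strand_overlaps = FALSE` to keep them.
#' Each aggregate is normalized according to `normalize`.
#'
#' @param profiles numeric matrix (transcripts x bins) or list of equal
#'   length profiles, aligned to `transcripts` rows.
#' @param transcripts a [transcript_table()].
#' @param classes biotypes to aggregate (default `mRNA, SUT, CUT, XUT`).
#' @param exclude_same_strand_overlaps drop same-strand overlapping
#'   transcripts among the aggregated classes (default `TRUE`).
#' @param normalize `"max"` (default; peak scaled to 1), `"sum"` (area 1)
#'   or `"none"`.
#' @return Named list per class: `profile` (numeric vector) and
#'   `n_transcripts`. Classes with no surviving transcripts are omitted
#'   with a warning.
#' @export
aggregate_by_class <- function(profiles, transcripts,
                               classes = c("mRNA", "SUT", "CUT", "XUT"),
                               exclude_same_strand_overlaps = TRUE,
                               normalize = c("max", "sum", "none")) {
  normalize <- match.arg(normalize)
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  stopifnot(nrow(profiles) == nrow(transcripts))
  sub_idx <- which(transcripts$biotype %in% classes)
  keep <- sub_idx
  if (exclude_same_strand_overlaps && length(sub_idx) > 1) {
    g <- .tx_granges(transcripts[sub_idx, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(g, ignore.strand = FALSE,
                                        drop.self = TRUE)
    bad <- unique(S4Vectors::queryHits(hits))
    keep <- sub_idx[setdiff(seq_along(sub_idx), bad)]
  }
  out <- list()
  for (cl in classes) {
    rows <- keep[transcripts$biotype[keep] == cl]
    if (!length(rows)) {
      warning("class ", cl, " has no transcripts after exclusion; omitted")
      next
    }
    prof <- colMeans(profiles[rows, , drop = FALSE])
    prof <- switch(normalize,
      max = if (max(prof) > 0) prof / max(prof) else prof,
      sum = if (sum(prof) > 0) prof / sum(prof) else prof,
      none = prof)
    out[[cl]] <- list(profile = prof, n_transcripts = length(rows))
  }
  out
}

#' Plot aggregated gene-body coverage profiles
#'
#' @param aggregates output of [aggregate_by_class()].
#' @param ... passed to [graphics::matplot()].
#' @return The input, invisibly.
#' @export
plot_coverage_profiles <- function(aggregates, ...) {
  m <- sapply(aggregates, function(a) a$profile)
  graphics::matplot(m, type = "l", lty = 1, xlab = "gene body percentile",
                    ylab = "normalized coverage", ...)
  graphics::legend("topleft", legend = colnames(m), lty = 1,
                   col = seq_len(ncol(m)), bty = "n")
  invisible(aggregates)
}
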