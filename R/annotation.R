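#' @importFrom methods as is
#' @importFrom stats median p.adjust pnorm rnbinom rnorm runif rlnorm rgamma
#'   var cor complete.cases setNames quantile plogis qlogis rbinom
#' @importFrom utils read.table write.table packageVersion
NULL

.BIOTYPES <- c("mRNA", "SUT", "CUT", "XUT", "snoRNA", "rRNA", "other")
.LNC_CLASSES <- c("SUT", "CUT", "XUT")

#' Build a stranded transcript table
#'
#' Transcripts are the unit of all per-gene statistics in this package. They
#' are stored as a plain data frame in 0-based half-open genomic coordinates
#' (BED convention); GTF input is converted on read. Multi-exon features are
#' collapsed to their genomic span.
#'
#' @param id character vector of unique transcript identifiers.
#' @param chrom chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand `"+"` or `"-"`.
#' @param biotype one of `mRNA`, `SUT`, `CUT`, `XUT`, `snoRNA`, `rRNA`,
#'   `other`. Unknown labels are mapped to `"other"` with a warning.
#' @return A `data.frame` of class `transcript_table` with columns
#'   `id, chrom, start, end, strand, biotype`.
#' @export
#' @examples
#' tx <- transcript_table(c("g1", "as1"), "chrI", c(0, 400), c(1000, 1400),
#'                        c("+", "-"), c("mRNA", "XUT"))
transcript_table <- function(id, chrom, start, end, strand, biotype) {
  tx <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   biotype = as.character(biotype),
                   stringsAsFactors = FALSE)
  unknown <- !(tx$biotype %in% .BIOTYPES)
  if (any(unknown)) {
    warning(sum(unknown), " transcript(s) with unknown biotype mapped to 'other'")
    tx$biotype[unknown] <- "other"
  }
  validate_transcripts(tx)
  class(tx) <- c("transcript_table", "data.frame")
  tx
}

#' Validate a transcript table
#'
#' Checks the structural invariants: unique ids, `0 <= start < end`, and
#' strands restricted to `+`/`-`.
#'
#' @param tx a data frame with columns `id, chrom, start, end, strand, biotype`.
#' @return `tx`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_transcripts <- function(tx) {
  need <- c("id", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(need, names(tx))
  if (length(miss)) stop("transcript table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tx$id))
    stop("duplicate transcript id(s): ",
         paste(unique(tx$id[duplicated(tx$id)]), collapse = ", "),
         call. = FALSE)
  if (any(tx$start < 0) || any(tx$end <= tx$start))
    stop("invalid interval(s): require 0 <= start < end")
  if (!all(tx$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(tx)
}

# internal: GRanges view of a transcript table (1-based closed for IRanges)
.tx_granges <- function(tx) {
  GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = tx$strand, id = tx$id, biotype = tx$biotype)
}

#' Overlap length between two genomic intervals
#'
#' Overlap in base pairs under the 0-based half-open convention; abutting
#' intervals overlap by 0, and intervals on different chromosomes never
#' overlap. Strand is deliberately ignored. Vectorised over rows.
#'
#' @param a,b data frames (or lists) with elements `chrom`, `start`, `end`.
#' @return Integer vector of overlap lengths (>= 0).
#' @export
#' @examples
#' overlap_bp(list(chrom = "c", start = 0, end = 10),
#'            list(chrom = "c", start = 5, end = 15))  # 5
overlap_bp <- function(a, b) {
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  as.integer(pmax(0L, ov) * (a$chrom == b$chrom))
}

#' Identify sense-antisense transcript pairs
#'
#' Finds all opposite-strand, same-chromosome overlapping pairs in which the
#' sense partner is an mRNA, keeping pairs whose overlap is at least
#' `min_fraction` of the reference length. asRNAs are typically the shorter
#' partner and the pairing is asRNA-centric, so the default denominator is
#' the antisense transcript's length; `denominator` switches the convention.
#'
#' @param tx a [transcript_table()].
#' @param min_fraction minimum overlap fraction in (0, 1]; the threshold is
#'   inclusive (`>=`). Default 0.5.
#' @param denominator which length the overlap fraction is relative to:
#'   `"antisense"` (default), `"sense"`, `"either"` (pass if either fraction
#'   qualifies) or `"reciprocal"` (both must qualify).
#' @param antisense_biotypes biotypes allowed as the antisense partner.
#' @return A `data.frame` with columns `sense_id, antisense_id, chrom,
#'   sense_start, overlap_bp, overlap_fraction`, sorted by
#'   `(chrom, sense_start)`. `overlap_fraction` is the fraction that governed
#'   the filter (for `"either"`, the larger of the two; for `"reciprocal"`,
#'   the smaller).
#' @export
#' @examples
#' tx <- transcript_table(c("g1", "as1"), "chrI", c(0, 400), c(1000, 1400),
#'                        c("+", "-"), c("mRNA", "XUT"))
#' find_pairs(tx)  # overlap 600 bp, fraction 0.6 of the asRNA
find_pairs <- function(tx, min_fraction = 0.5,
                       denominator = c("antisense", "sense", "either",
                                       "reciprocal"),
                       antisense_biotypes = c("SUT", "CUT", "XUT", "mRNA")) {
  denominator <- match.arg(denominator)
  validate_transcripts(tx)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  empty <- data.frame(sense_id = character(), antisense_id = character(),
                      chrom = character(), sense_start = integer(),
                      overlap_bp = integer(), overlap_fraction = numeric(),
                      stringsAsFactors = FALSE)
  sense <- tx[tx$biotype == "mRNA", , drop = FALSE]
  anti <- tx[tx$biotype %in% antisense_biotypes, , drop = FALSE]
  if (!nrow(sense) || !nrow(anti)) return(empty)
  gs <- .tx_granges(sense)
  ga <- .tx_granges(anti)
  hits <- GenomicRanges::findOverlaps(gs, ga, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  keep <- sense$strand[i] != anti$strand[j] & sense$id[i] != anti$id[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(empty)
  ov <- overlap_bp(sense[i, ], anti[j, ])
  len_s <- sense$end[i] - sense$start[i]
  len_a <- anti$end[j] - anti$start[j]
  frac <- switch(denominator,
    antisense  = ov / len_a,
    sense      = ov / len_s,
    either     = pmax(ov / len_a, ov / len_s),
    reciprocal = pmin(ov / len_a, ov / len_s))
  keep <- ov >= 1L & frac >= min_fraction
  out <- data.frame(sense_id = sense$id[i][keep],
                    antisense_id = anti$id[j][keep],
                    chrom = sense$chrom[i][keep],
                    sense_start = sense$start[i][keep],
                    overlap_bp = ov[keep],
                    overlap_fraction = frac[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$sense_start, out$sense_id, out$antisense_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict lncRNAs to class-exclusive transcripts
#'
#' SUTs, XUTs and CUTs are kept only if they have zero same-strand overlap
#' with a transcript of a *different* lncRNA class; both members of a
#' conflicting same-strand overlap are dropped. mRNAs and other biotypes pass
#' unchanged, and overlap with them never disqualifies a lncRNA.
#'
#' @param tx a [transcript_table()].
#' @return The filtered `transcript_table`.
#' @export
filter_exclusive_lncrnas <- function(tx) {
  validate_transcripts(tx)
  lnc <- tx[tx$biotype %in% .LNC_CLASSES, , drop = FALSE]
  if (nrow(lnc) < 2) return(tx)
  g <- .tx_granges(lnc)
  hits <- GenomicRanges::findOverlaps(g, ignore.strand = FALSE,
                                      drop.self = TRUE, drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  conflict <- lnc$biotype[i] != lnc$biotype[j]
  drop_ids <- unique(c(lnc$id[i[conflict]], lnc$id[j[conflict]]))
  out <- tx[!(tx$id %in% drop_ids), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' Read a transcript annotation from GTF
#'
#' Uses `rtracklayer` for parsing; features are collapsed to their genomic
#' span per transcript. GTF is 1-based closed on disk and converted to the
#' internal 0-based half-open convention. The biotype is taken from
#' `biotype_attr` (falling back to `"other"` when absent or unknown).
#'
#' @param path GTF file path.
#' @param id_attr attribute carrying the transcript id
#'   (default `"transcript_id"`, falling back to `"gene_id"`).
#' @param biotype_attr attribute carrying the biotype
#'   (default `"transcript_biotype"`, falling back to `"gene_biotype"`).
#' @return A [transcript_table()].
#' @export
read_gtf <- function(path, id_attr = "transcript_id",
                     biotype_attr = "transcript_biotype") {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  ids <- if (id_attr %in% names(md)) md[[id_attr]] else md[["gene_id"]]
  if (is.null(ids)) stop("GTF carries neither '", id_attr, "' nor 'gene_id'")
  bt <- if (biotype_attr %in% names(md)) md[[biotype_attr]]
        else if ("gene_biotype" %in% names(md)) md[["gene_biotype"]]
        else rep("other", length(gr))
  bt[is.na(bt)] <- "other"
  df <- data.frame(id = as.character(ids),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   biotype = as.character(bt), stringsAsFactors = FALSE)
  # collapse multi-exon / multi-row features to the transcript span
  sp <- split(df, df$id)
  df <- do.call(rbind, lapply(sp, function(d)
    data.frame(id = d$id[1], chrom = d$chrom[1], start = min(d$start),
               end = max(d$end), strand = d$strand[1], biotype = d$biotype[1],
               stringsAsFactors = FALSE)))
  transcript_table(df$id, df$chrom, df$start, df$end, df$strand, df$biotype)
}

#' Read a transcript annotation from BED6 plus a biotype sidecar
#'
#' BED is already 0-based half-open and passes through unchanged. Biotypes
#' come from a two-column tab-separated sidecar (`id`, `biotype`); ids absent
#' from the sidecar get biotype `"other"`.
#'
#' @param path BED6 file path (`name` column holds the transcript id).
#' @param biotype_tsv path to the id-to-biotype table (no header required;
#'   columns `id`, `biotype`).
#' @return A [transcript_table()].
#' @export
read_bed6 <- function(path, biotype_tsv = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids)) stop("BED file lacks the name column")
  bt <- rep("other", length(gr))
  if (!is.null(biotype_tsv)) {
    side <- read.table(biotype_tsv, header = FALSE, sep = "\t",
                       col.names = c("id", "biotype"),
                       stringsAsFactors = FALSE)
    m <- match(ids, side$id)
    bt[!is.na(m)] <- side$biotype[m[!is.na(m)]]
  }
  transcript_table(ids, as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   as.character(GenomicRanges::strand(gr)), bt)
}

#' Write a sense-antisense pair table to TSV
#'
#' @param pairs output of [find_pairs()].
#' @param path destination file.
#' @param header optional comment lines written before the table.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, header = NULL) {
  write_tsv(pairs[, c("sense_id", "antisense_id", "chrom", "overlap_bp",
                      "overlap_fraction")], path, header = header)
}

#' @export
print.transcript_table <- function(x, ...) {
  cat("Transcript annotation: ", nrow(x), " transcripts on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  print(table(factor(x$biotype, levels = .BIOTYPES)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("... and ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
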