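#' Per-transcript DMS structural change between strains
#'
#' Scores how much more accessible a transcript's nucleotides are in the
#' mutant (e.g. dbp2-delta) than in the wild type: the wild-type reactivity
#' summary is subtracted from the mutant's. The default summary is the mean
#' per-nucleotide reactivity (length-normalized; raw sums confound
#' transcript length), with `stat = "sum"` available.
#'
#' @param wt,mut numeric vectors of per-nucleotide DMS reactivities (>= 0)
#'   for the same transcript; equal lengths required.
#' @param stat `"mean"` (default) or `"sum"`.
#' @return `stat(mut) - stat(wt)`; positive values mean nucleotides became
#'   more accessible in the mutant.
#' @export
#' @examples
#' reactivity_delta(rep(1, 10), rep(2.5, 10))  # 1.5
reactivity_delta <- function(wt, mut, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  if (length(wt) != length(mut))
    stop("reactivity tracks differ in length (", length(wt), " vs ",
         length(mut), ")")
  if (any(wt < 0) || any(mut < 0)) stop("reactivities must be non-negative")
  f <- if (stat == "mean") mean else sum
  f(mut) - f(wt)
}

#' Reactivity deltas for many transcripts
#'
#' @param wt,mut named lists of per-nucleotide reactivity vectors; ids are
#'   matched by name and must agree.
#' @param stat passed to [reactivity_delta()].
#' @return Data frame `id, delta`.
#' @export
reactivity_delta_all <- function(wt, mut, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  ids <- names(wt)
  if (!setequal(ids, names(mut)))
    stop("wild-type and mutant reactivity sets cover different transcripts")
  data.frame(id = ids,
             delta = vapply(ids, function(i)
               reactivity_delta(wt[[i]], mut[[i]], stat), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean structural change per dsRNA-propensity group
#'
#' @param deltas numeric vector of per-transcript reactivity deltas.
#' @param groups propensity groups aligned with `deltas` (see
#'   [propensity_group()]).
#' @return Data frame `group, mean_delta, n`, sorted by group; empty groups
#'   are omitted.
#' @export
delta_by_propensity <- function(deltas, groups) {
  stopifnot(length(deltas) == length(groups))
  g <- factor(groups, levels = sort(unique(groups)))
  data.frame(group = as.integer(levels(g)),
             mean_delta = as.numeric(tapply(deltas, g, mean)),
             n = as.integer(table(g)), row.names = NULL)
}

#' Read a per-nucleotide reactivity table
#'
#' Expects a tab-separated file with columns `id`, `pos` (0-based) and
#' `reactivity`; returns one vector per transcript ordered by position.
#'
#' @param path TSV path.
#' @return Named list of numeric reactivity vectors.
#' @export
read_reactivity <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "pos", "reactivity")
  if (!all(need %in% names(df)))
    stop("reactivity table needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$id), function(d) d$reactivity[order(d$pos)])
}

#' Write per-nucleotide reactivity tables
#'
#' @param tracks named list of reactivity vectors.
#' @param path destination TSV.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_reactivity <- function(tracks, path, header = NULL) {
  df <- do.call(rbind, lapply(names(tracks), function(i)
    data.frame(id = i, pos = seq_along(tracks[[i]]) - 1L,
               reactivity = tracks[[i]], stringsAsFactors = FALSE)))
  write_tsv(df, path, header = header)
}
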