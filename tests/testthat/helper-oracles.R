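# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# all-vs-all O(n^2) sense-antisense pair scan on a transcript data frame
brute_force_pairs <- function(tx, min_fraction = 0.5,
                              antisense_biotypes = c("SUT", "CUT", "XUT",
                                                     "mRNA")) {
  out <- list()
  for (i in seq_len(nrow(tx))) {
    if (tx$biotype[i] != "mRNA") next
    for (j in seq_len(nrow(tx))) {
      if (i == j) next
      if (!(tx$biotype[j] %in% antisense_biotypes)) next
      if (tx$chrom[i] != tx$chrom[j]) next
      if (tx$strand[i] == tx$strand[j]) next
      ov <- min(tx$end[i], tx$end[j]) - max(tx$start[i], tx$start[j])
      if (ov < 1) next
      frac <- ov / (tx$end[j] - tx$start[j])
      if (frac >= min_fraction)
        out[[length(out) + 1]] <- data.frame(
          sense_id = tx$id[i], antisense_id = tx$id[j],
          overlap_bp = ov, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sense_id = character(), antisense_id = character(),
                      overlap_bp = integer()))
  do.call(rbind, out)
}

# textbook step-up Benjamini-Hochberg, written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (k in n:1) {
    running_min <- min(running_min, n / k * p[o[k]])
    adj[o[k]] <- min(1, running_min)
  }
  adj
}

# Spearman via the explicit rank formula (Pearson on mid-ranks)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random stranded annotation on a few chromosomes
random_annotation <- function(n, n_chrom = 3, chrom_len = 5e4) {
  start <- sample.int(chrom_len - 2000L, n, replace = TRUE)
  len <- sample(100:2000, n, replace = TRUE)
  transcript_table(
    id = sprintf("t%04d", seq_len(n)),
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(c("mRNA", "SUT", "CUT", "XUT", "snoRNA"), n,
                     replace = TRUE, prob = c(0.5, 0.15, 0.15, 0.15, 0.05)))
}

# pair tables as comparable canonical strings
pair_key <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$sense_id, df$antisense_id, df$overlap_bp, sep = "|"))
}
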