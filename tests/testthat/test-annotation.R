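test_that("interval overlap follows the 0-based half-open convention", {
  a <- list(chrom = "c", start = 0, end = 10)
  expect_identical(overlap_bp(a, list(chrom = "c", start = 5, end = 15)), 5L)
  expect_identical(overlap_bp(a, list(chrom = "c", start = 10, end = 20)), 0L)
  expect_identical(overlap_bp(a, list(chrom = "d", start = 5, end = 15)), 0L)
})

test_that("pairing applies the half-overlap rule on opposite strands", {
  tx <- transcript_table(
    id = c("g1", "as_in", "as_out", "same_strand"),
    chrom = "chrI",
    start = c(0, 400, 2600, 300),
    end = c(1000, 1400, 3600, 900),
    strand = c("+", "-", "-", "+"),
    biotype = c("mRNA", "XUT", "XUT", "SUT"))
  # as_in: overlap 600 of length 1000 -> 0.6 >= 0.5, paired
  p <- find_pairs(tx)
  expect_equal(p$sense_id, "g1")
  expect_equal(p$antisense_id, "as_in")
  expect_equal(p$overlap_bp, 600L)
  expect_equal(p$overlap_fraction, 0.6)
  # shifting the asRNA to overlap only 400/1000 = 0.4 drops the pair
  tx2 <- tx
  tx2$start[2] <- 600; tx2$end[2] <- 1600
  expect_equal(nrow(find_pairs(tx2)), 0L)
  # a same-strand overlap is never a pair, whatever the overlap
  tx3 <- transcript_table(c("g1", "s2"), "chrI", c(0, 100), c(1000, 900),
                          c("+", "+"), c("mRNA", "XUT"))
  expect_equal(nrow(find_pairs(tx3, min_fraction = 0.01)), 0L)
})

test_that("pairing rejects duplicate ids and handles empty input", {
  tx <- data.frame(id = c("a", "a"), chrom = "c", start = c(0, 10),
                   end = c(5, 20), strand = c("+", "-"),
                   biotype = c("mRNA", "XUT"))
  expect_error(find_pairs(tx), "duplicate transcript id")
  empty <- transcript_table(character(), character(), integer(), integer(),
                            character(), character())
  expect_equal(nrow(find_pairs(empty)), 0L)
})

test_that("pairing matches the all-vs-all brute-force scan", {
  set.seed(42)
  for (rep in 1:20) {
    tx <- random_annotation(sample(50:300, 1))
    got <- find_pairs(tx)
    want <- brute_force_pairs(as.data.frame(tx))
    expect_identical(pair_key(got), pair_key(want))
  }
})

test_that("pairing is order-invariant and monotone in min_fraction", {
  set.seed(7)
  tx <- random_annotation(200)
  perm <- tx[sample(nrow(tx)), ]
  class(perm) <- class(tx)
  expect_identical(pair_key(find_pairs(tx)), pair_key(find_pairs(perm)))
  fr <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  n_pairs <- sapply(fr, function(f) nrow(find_pairs(tx, min_fraction = f)))
  expect_true(all(diff(n_pairs) <= 0))
})

test_that("fraction denominator conventions behave as documented", {
  # sense 1000 bp, antisense 400 bp fully inside: frac(as) = 1, frac(sense) = 0.4
  tx <- transcript_table(c("g", "a"), "c", c(0, 100), c(1000, 500),
                         c("+", "-"), c("mRNA", "XUT"))
  expect_equal(nrow(find_pairs(tx, 0.5, denominator = "antisense")), 1L)
  expect_equal(nrow(find_pairs(tx, 0.5, denominator = "sense")), 0L)
  expect_equal(nrow(find_pairs(tx, 0.5, denominator = "either")), 1L)
  expect_equal(nrow(find_pairs(tx, 0.5, denominator = "reciprocal")), 0L)
})

test_that("lncRNA class exclusivity removes same-strand cross-class overlaps", {
  tx <- transcript_table(
    id = c("sut1", "xut1", "sut2", "xut2", "sut3", "m1"),
    chrom = "c",
    start = c(0, 500, 2000, 2000, 4000, 4100),
    end = c(1000, 1500, 3000, 3000, 5000, 4600),
    strand = c("+", "+", "+", "-", "+", "+"),
    biotype = c("SUT", "XUT", "SUT", "XUT", "SUT", "mRNA"))
  out <- filter_exclusive_lncrnas(tx)
  # sut1/xut1 same-strand cross-class: both removed
  expect_false(any(c("sut1", "xut1") %in% out$id))
  # sut2/xut2 opposite strands: both kept
  expect_true(all(c("sut2", "xut2") %in% out$id))
  # sut3 overlaps only an mRNA: kept, and the mRNA passes unchanged
  expect_true(all(c("sut3", "m1") %in% out$id))
})

test_that("GTF and BED6 readers round-trip an annotation", {
  tx <- transcript_table(c("g1", "as1"), "chrI", c(99, 400), c(1000, 1400),
                         c("+", "-"), c("mRNA", "XUT"))
  gtf <- tempfile(fileext = ".gtf"); bio <- tempfile(fileext = ".tsv")
  write_annotation(tx, gtf, bio)
  back <- read_gtf(gtf)
  back <- back[match(tx$id, back$id), ]
  expect_equal(back$start, tx$start)  # 1-based GTF converted back
  expect_equal(back$end, tx$end)
  expect_equal(back$biotype, tx$biotype)

  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", tx$chrom, tx$start, tx$end,
                     tx$id, tx$strand), bed)
  back2 <- read_bed6(bed, bio)
  back2 <- back2[match(tx$id, back2$id), ]
  expect_equal(back2$start, tx$start)
  expect_equal(back2$biotype, tx$biotype)
  # without a sidecar everything is biotype "other"
  expect_true(all(read_bed6(bed)$biotype == "other"))
})
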