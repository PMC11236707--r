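make_cm <- function(K, conds) {
  K <- as.matrix(K)
  rownames(K) <- sprintf("g%03d", seq_len(nrow(K)))
  samples <- data.frame(sample = paste0("s", seq_len(ncol(K))),
                        assay = "test", condition = conds,
                        replicate = ave(seq_along(conds), conds,
                                        FUN = seq_along))
  colnames(K) <- samples$sample
  count_matrix(K, samples)
}

test_that("low-count filter uses a strict mean threshold", {
  K <- rbind(rep(40, 4), c(100, 0, 100, 0), rep(0, 4), rep(41, 4))
  cm <- make_cm(K, c("a", "a", "b", "b"))
  kept <- rownames(filter_low_counts(cm)$counts)
  expect_identical(kept, c("g002", "g004"))  # mean 40 is out, 50 and 41 in
})

test_that("size factors follow median-of-ratios with unit geometric mean", {
  K1 <- matrix(rpois(40, 100), 10, 4)
  cm <- make_cm(cbind(K1[, 1], 2 * K1[, 1]), c("a", "b"))
  sf <- estimate_size_factors(cm)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  cm_same <- make_cm(K1[, c(1, 1, 1)], c("a", "a", "b"))
  expect_equal(unname(estimate_size_factors(cm_same)), rep(1, 3),
               tolerance = 1e-9)

  set.seed(1)
  K <- matrix(rpois(15, 50) + 1, 5, 3)
  sf <- estimate_size_factors(make_cm(K, c("a", "a", "b")))
  # hand-computed median-of-ratios
  geo <- exp(rowMeans(log(K)))
  raw <- apply(K / geo, 2, median)
  expect_equal(unname(sf), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)

  bad <- make_cm(rbind(c(0, 1, 2), c(3, 0, 1)), c("a", "a", "b"))
  expect_error(estimate_size_factors(bad), "positive counts in every sample")
})

test_that("BH adjustment equals the textbook step-up on random input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_identical(bh_adjust(c(0.1, NA, 0.5))[2], NA_real_)
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("log2 ratio applies the pseudocount only on zeros by default", {
  expect_equal(log2_ratio(8, 2, mode = "never"), 2)
  expect_equal(log2_ratio(7.3, 7.3), 0)
  expect_equal(log2_ratio(0, 4, pseudocount = 1), log2(1 / 5))
  expect_equal(log2_ratio(6, 2), log2(3))  # untouched when both positive
  expect_error(log2_ratio(0, 0, pseudocount = 0), "both zero")
})

test_that("Wald log2fc is exact for proportional counts and symmetric", {
  K <- cbind(2000, 2000, 2000, 1000, 1000, 1000)[rep(1, 5), ]
  cm <- make_cm(K, rep(c("num", "den"), each = 3))
  res <- nb_wald_test(cm, c("num", "den"), size_factors = rep(1, 6))
  expect_equal(res$log2fc, rep(1, 5))

  set.seed(2)
  K <- matrix(rnbinom(600, mu = 150, size = 20), 100, 6)
  cm <- make_cm(K, rep(c("a", "b"), each = 3))
  res_ab <- nb_wald_test(cm, c("a", "b"))
  # permuting samples within conditions changes nothing
  cm_perm <- make_cm(K[, c(3, 1, 2, 6, 5, 4)], rep(c("a", "b"), each = 3))
  res_perm <- nb_wald_test(cm_perm, c("a", "b"))
  expect_equal(res_ab$log2fc, res_perm$log2fc)
  expect_equal(res_ab$p, res_perm$p)
})

test_that("results are invariant to per-sample count scaling", {
  set.seed(3)
  K <- matrix(rnbinom(600, mu = 200, size = 10), 100, 6)
  cm <- make_cm(K, rep(c("a", "b"), each = 3))
  res1 <- nb_wald_test(cm, c("a", "b"))
  cj <- c(0.5, 1.3, 2, 0.8, 1.1, 1.7)
  cm2 <- make_cm(sweep(K, 2, cj, "*"), rep(c("a", "b"), each = 3))
  res2 <- nb_wald_test(cm2, c("a", "b"))
  expect_equal(res1$log2fc, res2$log2fc, tolerance = 1e-6)
})

test_that("zero-mean conditions are guarded and flagged", {
  K <- rbind(c(0, 0, 0, 50, 60, 55), c(100, 90, 110, 100, 95, 105))
  cm <- make_cm(K, rep(c("a", "b"), each = 3))
  res <- nb_wald_test(cm, c("a", "b"), size_factors = rep(1, 6))
  expect_true(res$zero_guard[1])
  expect_false(res$zero_guard[2])
  expect_true(is.finite(res$log2fc[1]))
})

test_that("enrichment_test reports untested transcripts with NA stats", {
  K <- rbind(rep(500, 6), rep(2, 6), rep(300, 6))
  cm <- make_cm(K, rep(c("a", "b"), each = 3))
  res <- enrichment_test(cm, c("a", "b"))
  expect_equal(res$tested, c(TRUE, FALSE, TRUE))
  expect_true(is.na(res$p[2]))
  expect_true(all(!is.na(res$p[c(1, 3)])))
  expect_equal(res$id, rownames(cm$counts))
})

test_that("log2fc estimates agree with DESeq2 on a shared simulation", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  G <- 150
  mu <- exp(rnorm(G, log(300), 0.8))
  lfc <- sample(c(0, 1, -1), G, replace = TRUE)
  K <- cbind(matrix(rnbinom(3 * G, mu = mu * 2^lfc, size = 20), G),
             matrix(rnbinom(3 * G, mu = mu, size = 20), G))
  cm <- make_cm(K, rep(c("trt", "ctl"), each = 3))
  ours <- nb_wald_test(cm, c("trt", "ctl"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = cm$counts,
    colData = data.frame(condition = factor(rep(c("trt", "ctl"), each = 3),
                                            levels = c("ctl", "trt"))),
    design = ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  theirs <- DESeq2::results(dds)
  expect_gt(cor(ours$log2fc, theirs$log2FoldChange, use = "complete.obs"),
            0.98)
  # size factors agree (same median-of-ratios definition up to rescaling)
  sf_ratio <- attr(ours, "size_factors") / DESeq2::sizeFactors(dds)
  expect_lt(diff(range(sf_ratio)), 1e-6)
})
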