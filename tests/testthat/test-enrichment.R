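test_that("median-of-ratios size factors have the defining properties", {
  m <- matrix(rpois(60, 50), ncol = 3)
  # identical samples -> all factors 1
  mm <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(compute_size_factors(mm)), rep(1, 3))
  # doubling a sample doubles its factor
  sf <- compute_size_factors(cbind(m[, 1], 2L * m[, 1]))
  expect_equal(sf[[2]] / sf[[1]], 2)
  # worked 3x3 example: factors proportional to (1, 2, 1)
  w <- matrix(c(10, 100, 4, 20, 200, 8, 10, 100, 4), ncol = 3)
  sfw <- compute_size_factors(w)
  expect_equal(unname(sfw / sfw[1]), c(1, 2, 1))
  # geometric mean rescaled to 1
  expect_equal(exp(mean(log(compute_size_factors(m)))), 1, tolerance = 1e-12)
  expect_error(compute_size_factors(matrix(c(0, 1, 1, 0), 2)),
               "normalization error")
})

test_that("size factors agree with DESeq2's estimator up to rescaling", {
  set.seed(14)
  mu <- rexp(200, 1 / 200)
  m <- sapply(c(1, 0.5, 2, 1.3), function(s) rpois(200, mu * s))
  ours <- compute_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]),
               tolerance = 1e-10)
})

test_that("moment dispersion estimates recover the truth", {
  set.seed(7)
  n <- 300
  cond <- rep(c("a", "b"), each = 25)
  mu <- runif(n, 100, 1000)
  pois <- sapply(seq_len(50), function(j) rpois(n, mu))
  a_pois <- estimate_dispersions(pois, rep(1, 50), cond)
  expect_lt(median(a_pois), 0.01)
  nb <- sapply(seq_len(50), function(j) rnbinom(n, mu = mu, size = 1 / 0.2))
  a_nb <- estimate_dispersions(nb, rep(1, 50), cond)
  expect_gt(median(a_nb), 0.1)
  expect_lt(median(a_nb), 0.3)
  expect_true(all(a_nb >= 1e-8))
  # unreplicated design falls back to the prior
  expect_warning(
    a1 <- estimate_dispersions(pois[, 1:2, drop = FALSE], c(1, 1),
                               c("a", "b"), prior_dispersion = 0.07),
    "prior dispersion")
  expect_equal(a1, rep(0.07, n))
})

make_samples <- function(counts, conds) {
  data.frame(sample = colnames(counts),
             condition = conds,
             replicate = ave(seq_along(conds), conds, FUN = seq_along))
}

toy_counts <- function(m) {
  rownames(m) <- format_variants(
    data.frame(position = seq_len(nrow(m)), wt_aa = "A", alt_aa = "V"))
  m
}

test_that("score_contrast computes pseudocounted log ratios of normalized means", {
  # identity contrast: selected columns identical to input columns
  set.seed(21)
  base <- matrix(rpois(40, 200), ncol = 2)
  counts <- toy_counts(cbind(base, base))
  colnames(counts) <- c("input_1", "input_2", "sel_1", "sel_2")
  smp <- make_samples(counts, c("input", "input", "sel", "sel"))
  res <- score_contrast(counts, smp, c("sel", "input"),
                        base_mean_threshold = 0)
  expect_equal(res$log2FoldChange, rep(0, 20))
  # closed form: balanced rows keep size factors at 1, 400/100 -> log2fc 2
  counts2 <- toy_counts(matrix(c(100, 400, 200, 100, 400, 200,
                                 400, 100, 200, 400, 100, 200),
                               ncol = 4))
  colnames(counts2) <- c("input_1", "input_2", "sel_1", "sel_2")
  smp2 <- make_samples(counts2, c("input", "input", "sel", "sel"))
  res2 <- score_contrast(counts2, smp2, c("sel", "input"),
                         base_mean_threshold = 0, pseudocount = 0)
  expect_equal(res2$log2FoldChange, c(2, -2, 0))
  # antisymmetry under contrast swap
  res2r <- score_contrast(counts2, smp2, c("input", "sel"),
                          base_mean_threshold = 0, pseudocount = 0)
  expect_equal(res2r$log2FoldChange, -res2$log2FoldChange)
  expect_error(score_contrast(counts2, smp2, c("sel", "nope")),
               "input error")
})

test_that("the baseMean filter and BH adjustment are applied exactly", {
  fx <- small_screen()
  res <- fx$s0
  expect_equal(sum(res$passed_filter), sum(res$baseMean >= 50))
  expect_true(all(is.na(res$padj[!res$passed_filter])))
  expect_true(all(!is.na(res$padj[res$passed_filter])))
  # BH over the passed-filter variants only, vs brute-force oracle
  p <- res$pvalue[res$passed_filter]
  expect_equal(res$padj[res$passed_filter], bh_oracle(p), tolerance = 1e-12)
  expect_true(all(res$padj >= res$pvalue, na.rm = TRUE))
  # padj monotone nondecreasing in p-value rank
  o <- order(p)
  expect_true(all(diff(res$padj[res$passed_filter][o]) >= -1e-15))
})

test_that("BH oracle reproduces the textbook example", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
})

test_that("sample PCA separates conditions and conserves variance", {
  fx <- small_screen()
  pca <- sample_pca(fx$screen$counts)
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-8)
  # silhouette of condition groups on the first two components > 0
  xy <- pca$coords[, 1:2]
  cond <- fx$screen$samples$condition
  d <- as.matrix(dist(xy))
  sil <- sapply(seq_along(cond), function(i) {
    a <- mean(d[i, cond == cond[i] & seq_along(cond) != i])
    b <- min(sapply(setdiff(unique(cond), cond[i]),
                    function(g) mean(d[i, cond == g])))
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0)
  # duplicated sample groups collapse to a point
  cdup <- fx$screen$counts[, c(1, 1, 2, 2, 3, 3)]
  colnames(cdup) <- paste0("s", 1:6)
  p2 <- sample_pca(cdup)
  expect_lt(max(abs(p2$coords[1, ] - p2$coords[2, ])), 1e-8)
  expect_error(sample_pca(fx$screen$counts[, 1:2]), "QC error")
})
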