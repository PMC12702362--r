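test_that("normalized position counts are enriched fractions", {
  sc <- data.frame(position = rep(c(3, 8, 20), c(19, 19, 19)),
                   log2FoldChange = c(rep(1, 19),
                                      rep(-1, 19),
                                      c(rep(0.5, 7), rep(-0.5, 12))))
  npc <- normalized_position_counts(sc)
  expect_equal(npc$npc, c(1, 0, 7 / 19))
  expect_equal(npc$npc[3], 0.3684, tolerance = 1e-4)
  expect_true(all(npc$npc >= 0 & npc$npc <= 1))
  # refined flag and passed_filter are honoured
  sc$refined <- sc$position != 8
  expect_equal(normalized_position_counts(sc)$position, c(3, 20))
})

test_that("conservation regression has the OLS closed-form properties", {
  npc <- data.frame(position = 1:5, npc = c(0.1, 0.3, 0.5, 0.7, 0.9))
  cons <- data.frame(position = 1:5, conservation = 2 * npc$npc)
  r <- suppressWarnings(conservation_regression(npc, cons))  # perfect fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$R2, 1, tolerance = 1e-12)
  expect_equal(r$n, 5)
  cons0 <- data.frame(position = 1:5, conservation = rep(1.3, 5))
  r0 <- conservation_regression(npc, cons0)
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_equal(r0$R2, 0, tolerance = 1e-12)
  # R^2 equals the squared Pearson correlation
  set.seed(6)
  cons2 <- data.frame(position = 1:5, conservation = rnorm(5))
  r2 <- conservation_regression(npc, cons2)
  expect_equal(r2$R2, cor(npc$npc, cons2$conservation)^2, tolerance = 1e-10)
  expect_error(conservation_regression(
    data.frame(position = 1:5, npc = rep(0.5, 5)), cons),
    "regression error")
  expect_error(conservation_regression(npc[1:2, ], cons), "regression error")
})

mk_npc <- function(pos, v) data.frame(position = pos, npc = v,
                                      n_scored = 19L)

test_that("quadrant labels follow the Cartesian convention", {
  pos <- 1:8
  x <- c(0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.9, 0.9)
  y <- c(0.9, 0.8, 0.9, 0.8, 0.1, 0.2, 0.1, 0.2)
  cons <- data.frame(position = pos, conservation = c(1, 2, 3, 4, 5, 6, 7, 8))
  qa <- quadrant_analysis(mk_npc(pos, x), mk_npc(pos, y), cons)
  expect_equal(as.character(qa$data$quadrant),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  # Q4 is the high-x / low-y corner
  expect_equal(qa$data$position[qa$data$quadrant == "Q4"], 7:8)
  # labels partition all positions
  expect_equal(sum(table(qa$data$quadrant)), 8)
  # points exactly at a median fall in the low half (both axes)
  pos9 <- 1:9
  x2 <- c(0.2, 0.2, 0.5, 0.5, 0.8, 0.8, 0.8, 0.8, 0.2)  # median 0.5
  y2 <- c(0.9, 0.9, 0.1, 0.1, 0.9, 0.9, 0.1, 0.1, 0.1)  # median 0.1
  cons9 <- data.frame(position = pos9, conservation = rnorm(9))
  qa2 <- quadrant_analysis(mk_npc(pos9, x2), mk_npc(pos9, y2), cons9)
  expect_equal(as.character(qa2$data$quadrant[3:4]), c("Q3", "Q3"))
  expect_equal(as.character(qa2$data$quadrant),
               c("Q2", "Q2", "Q3", "Q3", "Q1", "Q1", "Q4", "Q4", "Q3"))
})

test_that("constant conservation yields a zero one-way F", {
  pos <- 1:8
  x <- c(0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.9, 0.9)
  y <- c(0.9, 0.8, 0.9, 0.8, 0.1, 0.2, 0.1, 0.2)
  cons <- data.frame(position = pos, conservation = rep(2, 8))
  qa <- quadrant_analysis(mk_npc(pos, x), mk_npc(pos, y), cons)
  expect_equal(qa$anova$F, 0)
})

test_that("Tukey adjusted p values match the studentized-range oracle", {
  set.seed(12)
  pos <- 1:24
  x <- rep(c(0.1, 0.9), each = 12)
  y <- rep(c(0.1, 0.9, 0.1, 0.9), each = 6)
  cons <- data.frame(position = pos,
                     conservation = rnorm(24) + rep(c(0, 1, 0, 2), each = 6))
  qa <- quadrant_analysis(mk_npc(pos, x), mk_npc(pos, y), cons)
  # brute-force Tukey-Kramer from first principles
  m <- merge(merge(setNames(mk_npc(pos, x)[1:2], c("position", "x")),
                   setNames(mk_npc(pos, y)[1:2], c("position", "y")),
                   by = "position"), cons, by = "position")
  g <- qa$data$quadrant
  k <- nlevels(g); n <- length(g)
  mse <- sum(tapply(qa$data$conservation, g, function(v)
    sum((v - mean(v))^2))) / (n - k)
  means <- tapply(qa$data$conservation, g, mean)
  sizes <- tapply(qa$data$conservation, g, length)
  for (i in seq_len(nrow(qa$tukey))) {
    pair <- strsplit(qa$tukey$comparison[i], "-")[[1]]
    se <- sqrt(mse / 2 * (1 / sizes[pair[1]] + 1 / sizes[pair[2]]))
    q <- abs(means[pair[1]] - means[pair[2]]) / se
    p_oracle <- ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE)
    expect_equal(qa$tukey$p_adj[i], unname(p_oracle), tolerance = 1e-8)
  }
})

test_that("empty quadrants raise an informative error", {
  pos <- 1:6
  x <- c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  y <- x  # perfectly correlated: Q2 and Q4 empty
  cons <- data.frame(position = pos, conservation = rnorm(6))
  expect_error(quadrant_analysis(mk_npc(pos, x), mk_npc(pos, y), cons),
               "analysis error.*Q2.*Q4")
})

test_that("two-way ANOVA matches a hand-worked sums-of-squares oracle", {
  # balanced 2x2 design, cell means (0, 0, 0, 1), 3 replicates per cell
  a <- factor(rep(c("lo", "hi"), each = 6))
  b <- factor(rep(rep(c("lo", "hi"), each = 3), 2))
  mu <- ifelse(a == "hi" & b == "hi", 1, 0)
  set.seed(19)
  y <- mu + rnorm(12, 0, 0.1)
  res <- two_way_anova(a, b, y)
  # independent oracle: type-II SS from residual sums of nested fits
  # computed with hand-built dummy design matrices and qr()
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  one <- rep(1, 12)
  A <- as.numeric(a == "hi"); B <- as.numeric(b == "hi")
  ss_a <- rss(cbind(one, B)) - rss(cbind(one, A, B))
  ss_b <- rss(cbind(one, A)) - rss(cbind(one, A, B))
  ss_ab <- rss(cbind(one, A, B)) - rss(cbind(one, A, B, A * B))
  mse <- rss(cbind(one, A, B, A * B)) / 8
  expect_equal(res$inhibition$F, ss_a / mse, tolerance = 1e-10)
  expect_equal(res$stability$F, ss_b / mse, tolerance = 1e-10)
  expect_equal(res$interaction$F, ss_ab / mse, tolerance = 1e-10)
  expect_equal(res$interaction$df, c(1, 8))
  # noise-free textbook decomposition: interaction SS = 3 * 4 * 0.25^2
  rss0 <- function(X) sum(qr.resid(qr(X), mu)^2)
  expect_equal(rss0(cbind(one, A, B)) - rss0(cbind(one, A, B, A * B)),
               0.75, tolerance = 1e-12)
  # degenerate designs
  expect_error(two_way_anova(a, factor(rep("x", 12)), y), "design error")
  expect_error(two_way_anova(a, a, y), "design error")
})

test_that("p values are calibrated when conservation ignores both factors", {
  set.seed(23)
  a <- factor(rep(c("lo", "hi"), each = 30))
  b <- factor(rep(rep(c("lo", "hi"), each = 15), 2))
  ps <- replicate(200, two_way_anova(a, b, rnorm(60))$interaction$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("one-way quadrant F equals the full two-way model F", {
  fx <- default_screen()
  scr <- fx$screen
  npc0 <- normalized_position_counts(fx$s0)
  npc48 <- normalized_position_counts(fx$refined,
                                      "functional_stability_score")
  qa <- quadrant_analysis(npc0, npc48, scr$conservation)
  d <- qa$data
  full <- summary(lm(conservation ~ (npc_0h > qa$medians[1]) *
                       (npc_48h > qa$medians[2]), data = d))
  expect_equal(qa$anova$F, unname(full$fstatistic[1]), tolerance = 1e-8)
  # npc tables only contain positions scored in the respective screens
  expect_true(all(qa$data$position %in%
                    intersect(npc0$position, npc48$position)))
})
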