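test_that("ground truth enumerates the full substitution space", {
  cfg <- sim_config(L = 379L, missing_fraction = 0)
  gt <- generate_ground_truth(cfg)
  expect_equal(nrow(gt$variants), 7201L)
  expect_true(all(gt$variants$present))
  expect_true(all(gt$variants$alt_aa != gt$variants$wt_aa))
  expect_equal(as.integer(table(gt$variants$position)),
               rep(19L, 379L))
})

test_that("present-variant fraction matches 1 - missing_fraction within 1", {
  for (mf in c(0.045, 0.2, 0.5)) {
    cfg <- sim_config(L = 80L, missing_fraction = mf, seed = 3)
    gt <- generate_ground_truth(cfg)
    expect_lte(abs(sum(gt$variants$present) - (1 - mf) * 19 * 80), 1)
  }
})

test_that("degenerate config gives wild-type-like ground truth throughout", {
  cfg <- small_config(include_nonfunctional = FALSE,
                      stabilized_half_life_multiplier = 1)
  gt <- generate_ground_truth(cfg)
  expect_true(all(gt$variants$half_life >= cfg$wt_half_life_range[1] &
                    gt$variants$half_life <= cfg$wt_half_life_range[2]))
  expect_true(all(gt$variants$activity >= cfg$functional_activity_range[1]))
})

test_that("the generator is deterministic under a fixed seed", {
  g1 <- generate_ground_truth(small_config(seed = 42))
  g2 <- generate_ground_truth(small_config(seed = 42))
  expect_identical(g1$variants, g2$variants)
  expect_identical(g1$positions, g2$positions)
  s1 <- simulate_screen(small_config(seed = 42))
  s2 <- simulate_screen(small_config(seed = 42))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$predictors, s2$predictors)
  expect_identical(s1$conservation, s2$conservation)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(L = 0), "configuration error")
  expect_error(sim_config(missing_fraction = 1.2), "configuration error")
  expect_error(sim_config(dispersion = -0.1), "configuration error")
  expect_error(sim_config(spike_ins = data.frame(variant = "I91L",
                                                 frequency = 1.0)),
               "configuration error")
  expect_error(sim_config(planted_regions = data.frame(start = 300,
                                                       end = 500)),
               "configuration error")
})

test_that("selection follows capture = activity * 2^(-t/h)", {
  # no decay at t = 0
  f <- c(0.25, 0.25, 0.5)
  a <- c(1, 0.5, 0.1)
  h <- c(1.5, 1.5, 1.5)
  expect_equal(simulate_selection(f, a, h, 0), f * a / sum(f * a))
  # closed-form decay factor: 48 h at h = 1.5 is 2^-32
  one <- simulate_selection(c(0.5, 0.5), c(1, 1), c(1.5, Inf), 48)
  expect_equal(one[1] / one[2], 2^-32, tolerance = 1e-12)
  # hand-computed two-variant normalization
  two <- simulate_selection(c(0.5, 0.5), c(1, 1), c(2, 4), 2)
  expect_equal(two, c(2^-1, 2^-0.5) / sum(c(2^-1, 2^-0.5)), tolerance = 1e-12)
  expect_equal(round(two, 3), c(0.414, 0.586))
  expect_equal(sum(two), 1, tolerance = 1e-12)
  expect_error(simulate_selection(c(0.5, 0.5), c(0, 0), c(1, 1), 10),
               "degenerate selection")
})

test_that("selection composes across incubation times (memorylessness)", {
  set.seed(5)
  f <- runif(50); f <- f / sum(f)
  h <- runif(50, 1, 40)
  a <- rep(1, 50)
  for (tt in list(c(1, 3), c(10, 38), c(0, 7))) {
    twice <- simulate_selection(simulate_selection(f, a, h, tt[1]),
                                a, h, tt[2])
    once <- simulate_selection(f, a, h, sum(tt))
    expect_equal(twice, once, tolerance = 1e-12)
    expect_equal(sum(twice), 1, tolerance = 1e-12)
  }
})

test_that("read counts reproduce the target frequencies and noise model", {
  set.seed(9)
  f <- runif(100, 0.5, 1.5); f <- f / sum(f)
  # multinomial mode: exact column sums, frequencies recovered at depth 1e7
  cm <- sample_read_counts(f, 1e7, replicates = 2, dispersion = 0,
                           condition = "input")
  expect_true(all(colSums(cm) == 1e7))
  expect_lt(max(abs(cm[, 1] / 1e7 - f) / f), 0.01)
  # negative-binomial mode: var/mean relation 1 + dispersion * mean
  f2 <- rep(1 / 50, 50)
  cn <- sample_read_counts(f2, 5e4, replicates = 1000, dispersion = 0.1,
                           condition = "x")
  ratio <- apply(cn, 1, var) / rowMeans(cn)
  expect_equal(mean(ratio), 1 + 0.1 * 5e4 / 50, tolerance = 0.2)
  expect_true(all(cn >= 0) && all(cn == round(cn)))
  expect_error(sample_read_counts(f2, 100, dispersion = -1),
               "configuration error")
  set.seed(33); c1 <- sample_read_counts(f2, 1000, 3, 0.05)
  set.seed(33); c2 <- sample_read_counts(f2, 1000, 3, 0.05)
  expect_identical(c1, c2)
})

test_that("predictor tables track function but not half-life", {
  cfg <- small_config(L = 220L, seed = 21)
  gt <- generate_ground_truth(cfg)
  # noise-free: VEP is a deterministic map of activity and the ddG gap
  # between misfolded and functional groups equals the penalty exactly
  pt0 <- generate_predictor_tables(gt, vep_noise_sd = 0, ddg_noise_sd = 0)
  same_a <- which(duplicated(gt$variants$activity) |
                    duplicated(gt$variants$activity, fromLast = TRUE))
  expect_equal(pt0$vep_score[gt$variants$functional],
               pmin(1, pmax(0, 0.85 - 0.75 *
                              gt$variants$activity[gt$variants$functional])))
  fun <- gt$variants$functional
  expect_equal(mean(pt0$ddg_active[!fun]) - mean(pt0$ddg_active[fun]),
               cfg$misfold_penalty, tolerance = 1e-12)
  expect_equal(mean(pt0$ddg_latent[!fun]) - mean(pt0$ddg_latent[fun]),
               cfg$misfold_penalty, tolerance = 1e-12)
  # ddG carries no half-life signal among functional variants
  pt <- generate_predictor_tables(gt)
  r <- cor(pt$ddg_latent[fun], gt$variants$half_life[fun])
  expect_lt(abs(r), 0.05)
  expect_gt(sum(fun), 1800)  # enough variants for the check to bite
})

test_that("conservation scores follow the planted tolerance model", {
  cfg <- small_config(seed = 13,
                      planted_regions = data.frame(start = integer(0),
                                                   end = integer(0)))
  gt <- generate_ground_truth(cfg)
  # alpha = beta = 0, no noise: identically zero
  z <- generate_conservation_scores(gt, alpha = 0, beta = 0, noise_sd = 0)
  expect_true(all(z$conservation == 0))
  # noise-free with tol48 = 0 everywhere: OLS recovers alpha exactly
  cs <- generate_conservation_scores(gt, alpha = 2.4, beta = 0.7,
                                     noise_sd = 0)
  fit <- lm(cs$conservation ~ gt$positions$tol0)
  expect_equal(unname(coef(fit)[2]), 2.4, tolerance = 1e-10)
  set.seed(2); g1 <- generate_conservation_scores(gt)
  set.seed(2); g2 <- generate_conservation_scores(gt)
  expect_identical(g1, g2)
})

test_that("simulated screens have coherent structure", {
  fx <- small_screen()
  scr <- fx$screen
  expect_true(all(scr$counts >= 0))
  expect_equal(nrow(scr$samples), 9L)
  expect_equal(sum(scr$input_freqs), 1, tolerance = 1e-12)
  expect_setequal(unique(scr$samples$condition),
                  c("input", "sel0h", "sel48h"))
  expect_equal(nrow(scr$counts), sum(scr$truth$variants$present))
})
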