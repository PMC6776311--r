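test_that("delta notation behaves as per-mil deviation from the standard", {
  expect_equal(delta_value(0.0036765, 0.0036765), 0)
  expect_equal(delta_value(1.0034 * 0.0036765, 0.0036765), 3.4,
               tolerance = 1e-9)
  expect_lt(delta_value(0.9 * 0.0036765, 0.0036765), 0)
  expect_error(delta_value(1, 0), "positive")
  # strictly increasing in r_sample
  expect_true(all(diff(delta_value(seq(0.9, 1.1, 0.01), 1)) > 0))
})

test_that("Levene W matches the ANOVA-on-absolute-deviations hand formula", {
  x1 <- c(1.2, 3.4, 2.2, 5.1)
  x2 <- c(2.0, 2.1, 6.3, 4.4, 3.3)
  got <- levene_test(c(x1, x2), rep(c("a", "b"), c(4, 5)), center = "mean")
  # hand computation: one-way F on z_ij = |x_ij - xbar_i|
  z1 <- abs(x1 - mean(x1)); z2 <- abs(x2 - mean(x2))
  zb <- mean(c(z1, z2))
  ssb <- 4 * (mean(z1) - zb)^2 + 5 * (mean(z2) - zb)^2
  ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  W_hand <- (ssb / 1) / (ssw / 7)
  expect_equal(got$W, W_hand, tolerance = 1e-10)
  expect_equal(got$p, stats::pf(W_hand, 1, 7, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("variance niche: group variances, shift invariance, scaling", {
  samples <- tibble::tibble(
    river = rep(c("A", "B"), each = 3), year = 2015L,
    d15N = c(1, 2, 3, 4, 5, 6), d13C = -c(25, 26, 27, 25, 27, 29))
  vn <- variance_niche(samples, "d15N")
  expect_equal(vn$group_stats$variance, c(1, 1))
  # identical spreads after a pure shift: W = 0, p = 1
  expect_equal(vn$omnibus$W, 0, tolerance = 1e-12)
  expect_equal(vn$omnibus$p, 1, tolerance = 1e-12)

  # Levene invariant under adding a constant to one group
  shifted <- samples
  shifted$d13C[shifted$river == "A"] <- shifted$d13C[shifted$river == "A"] + 7
  expect_equal(variance_niche(shifted, "d13C")$omnibus$W,
               variance_niche(samples, "d13C")$omnibus$W, tolerance = 1e-12)

  # sample variance scales quadratically
  scaled <- samples
  scaled$d15N <- 3 * scaled$d15N
  expect_equal(variance_niche(scaled, "d15N")$group_stats$variance,
               9 * vn$group_stats$variance)

  tiny <- samples[-(1:2), ]
  expect_error(variance_niche(tiny, "d15N"), "fewer than 2")
})

test_that("normality check is advisory with explicit degenerate verdicts", {
  set.seed(31)
  verdicts <- replicate(20, normality_check(rnorm(50))$verdict)
  expect_gte(mean(verdicts == "normal"), 0.8)
  expect_warning(nc <- normality_check(c(1, 2)), "not assessed")
  expect_equal(nc$verdict, "not assessed")
  expect_warning(ncc <- normality_check(rep(5, 10)), "degenerate")
  expect_equal(ncc$verdict, "degenerate")
})

test_that("two-factor ANOVA matches the textbook sums-of-squares split", {
  # balanced 2x2 with 3 replicates per cell
  y <- c(10, 11, 12,  14, 15, 16,  20, 21, 22,  30, 31, 32)
  riv <- rep(c("A", "B"), each = 6)
  yr <- rep(rep(c(1, 2), each = 3), 2)
  tab <- anova_two_factor(y, riv, yr)
  # hand decomposition for a balanced design
  gm <- mean(y)
  cell <- tapply(y, list(riv, yr), mean)
  ssr <- 6 * sum((rowMeans(cell) - gm)^2)
  ssy <- 6 * sum((colMeans(cell) - gm)^2)
  ssc <- 3 * sum((cell - outer(rowMeans(cell) - gm, colMeans(cell) - gm, "+")
                  - gm)^2)
  fitted <- cell[cbind(match(riv, c("A", "B")), yr)]
  sse <- sum((y - fitted)^2)
  expect_equal(tab$sumsq[tab$term == "river"], ssr, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "year"], ssy, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "river:year"], ssc, tolerance = 1e-10)
  expect_equal(sum(tab$sumsq), sum((y - gm)^2), tolerance = 1e-10)

  # equal cell means -> both factor F near zero
  y0 <- rep(c(5, 6, 7), 4)
  tab0 <- anova_two_factor(y0, riv, yr)
  expect_lt(max(tab0$statistic[1:2]), 1e-10)

  expect_error(anova_two_factor(rep(1:3, 4), riv, yr, log_transform = FALSE),
               NA)
  expect_error(anova_two_factor(c(-1, y[-1]), riv, yr, log_transform = TRUE),
               "positive")
  expect_error(anova_two_factor(rep(1, 12), riv, yr), "at least two|residual",
               ignore.case = TRUE)
  expect_error(anova_two_factor(y[1:9], riv[1:9], yr[1:9]), "empty design")
})

test_that("pairwise t tests honor the variance policy and Bonferroni", {
  x <- c(1.1, 2.2, 3.3, 4.4)
  g <- rep(c("a", "b"), each = 2)
  same <- pairwise_t_bonferroni(c(x[1:2], x[1:2]), g,
                                equal_var_policy = "pooled")
  expect_equal(same$t, 0)
  expect_equal(same$p_adj, 1)

  # Welch df hand oracle
  x1 <- c(3.1, 4.5, 2.2, 6.6, 5.0)
  x2 <- c(10.0, 10.4, 9.8)
  res <- pairwise_t_bonferroni(c(x1, x2), rep(c("a", "b"), c(5, 3)),
                               equal_var_policy = "welch")
  v1 <- var(x1) / 5; v2 <- var(x2) / 3
  df_hand <- (v1 + v2)^2 / (v1^2 / 4 + v2^2 / 2)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_adj, res$p_raw)  # single contrast: m = 1

  # with three groups p_adj = 3 * p_raw, capped, and never below raw
  set.seed(13)
  v <- rnorm(30)
  gg <- rep(c("a", "b", "c"), each = 10)
  all3 <- pairwise_t_bonferroni(v, gg)
  expect_equal(nrow(all3), 3L)
  expect_true(all(all3$p_adj >= all3$p_raw))
  expect_true(all(all3$p_adj <= 1))
  expect_equal(all3$p_adj, pmin(1, all3$p_raw * 3))

  expect_error(pairwise_t_bonferroni(v, gg, contrasts = list(c("a", "zz"))),
               "unknown group")
})
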