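# Nonparametric group statistics and mode-wise clinical regression.

test_that("Kruskal-Wallis H matches the exact rank formula", {
  # ranks 1,2 vs 3,4: H = 12/(4*5) * (2*(1.5-2.5)^2 + 2*(3.5-2.5)^2) = 2.4
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$statistic, 2.4, tolerance = 1e-12)
  expect_equal(kw$df, 1L)

  same <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # invariance under strictly monotone transforms
  set.seed(1)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(exp(v), g)$statistic,
               kruskal_wallis(v, g)$statistic, tolerance = 1e-12)
  # and under input reordering
  o <- sample(30)
  expect_equal(kruskal_wallis(v[o], g[o])$statistic,
               kruskal_wallis(v, g)$statistic, tolerance = 1e-12)
  expect_error(kruskal_wallis(v, rep("a", 30)), ">= 2")
})

test_that("Dunn z reduces to the two-group rank-sum normal approximation", {
  set.seed(2)
  a <- rnorm(8); b <- rnorm(11) + 1   # tie-free continuous data
  d <- dunn_posthoc_bh(c(a, b), rep(c("a", "b"), c(8, 11)))
  expect_equal(nrow(d), 1L)
  # Wilcoxon rank-sum normal approximation (no continuity correction)
  r <- rank(c(a, b)); W <- sum(r[1:8])
  z_or <- (W - 8 * (8 + 11 + 1) / 2) / sqrt(8 * 11 * (8 + 11 + 1) / 12)
  expect_equal(abs(d$z), abs(z_or), tolerance = 1e-10)
  expect_equal(d$p, 2 * pnorm(-abs(z_or)), tolerance = 1e-10)

  # three groups -> three pairwise rows; BH keeps p_adj >= p, <= 1, monotone
  v <- c(a, b, rnorm(6) + 2); g <- rep(c("a", "b", "c"), c(8, 11, 6))
  d3 <- dunn_posthoc_bh(v, g)
  expect_equal(nrow(d3), 3L)
  expect_true(all(d3$p_adj >= d3$p - 1e-15) && all(d3$p_adj <= 1))
  expect_equal(order(d3$p), order(d3$p_adj))
  expect_equal(d3$p_adj, p.adjust(d3$p, "BH"))

  # monotone-transform invariance of the rank machinery
  d3t <- dunn_posthoc_bh(exp(v), g)
  expect_equal(d3t$z, d3$z, tolerance = 1e-12)

  # BH fixed point: all raw p equal -> adjusted equals raw
  equalp <- p.adjust(rep(0.2, 3), "BH")
  expect_equal(equalp, rep(0.2, 3))
  expect_error(dunn_posthoc_bh(v, factor(g, levels = c("a", "b", "c", "d"))[
    seq_along(v)]), NA)
})

test_that("Cohen's d uses the pooled n-1 standard deviation", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 3), c(2, 4)), -cohens_d(c(2, 4), c(1, 3)))
  expect_error(cohens_d(rep(1, 3), rep(1, 4)), "zero pooled sd")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("Spearman correlation handles monotone data, ties and NAs", {
  x <- c(1, 4, 9, 16, 25); y <- exp(x / 10)
  expect_equal(spearman_correlation(x, y)$rho, 1)
  expect_equal(spearman_correlation(x, rev(y))$rho, -1)

  xt <- c(1, 2, 2, 3, 5, 7); yt <- c(2, 1, 4, 4, 6, 8)  # ties in both
  ours <- spearman_correlation(xt, yt)
  oracle <- suppressWarnings(cor.test(xt, yt, method = "spearman",
                                      exact = FALSE))
  expect_equal(ours$rho, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-9)

  withNA <- suppressMessages(spearman_correlation(c(x, NA), c(y, 1)))
  expect_equal(withNA$n_used, 5L)
  expect_equal(withNA$n_dropped, 1L)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 2:1), ">= 3")
})

test_that("mode-wise GLM recovers exact linear structure and matches F", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("mode_", c(1, 9, 13))))
  y <- 2 + 1.5 * x[, 1] - 3 * x[, 2] + 0.5 * x[, 3]
  fit <- suppressWarnings(modewise_glm(y, x))
  expect_lt(attr(fit, "sigma")^2 * (20 - 4), 1e-16)
  expect_equal(fit$estimate, c(2, 1.5, -3, 0.5), tolerance = 1e-8)
  expect_equal(sign(fit$estimate[-1]), c(1, -1, 1))

  # single predictor: t^2 equals the regression F statistic
  y1 <- y + rnorm(20)
  f1 <- modewise_glm(y1, x[, 1, drop = FALSE])
  lmf <- summary(lm(y1 ~ x[, 1]))
  expect_equal(f1$t[2]^2, unname(lmf$fstatistic[1]), tolerance = 1e-10)

  # collinear predictors are rejected with the offending columns named
  xc <- cbind(x[, 1:2], mode_13 = x[, 1] * 2 + 1e-12 * rnorm(20))
  expect_error(modewise_glm(y1, xc), "collinear.*mode_1")
  expect_error(modewise_glm(y1[1:4], x[1:4, ]), "complete cases")
})

test_that("distribution diagnostics run but never gate the pipeline", {
  set.seed(5)
  v <- c(rnorm(15), rexp(15)); g <- rep(c("a", "b"), each = 15)
  d <- distribution_diagnostics(v, g)
  expect_equal(nrow(d$shapiro), 2L)
  expect_true(is.finite(d$levene$p))
})
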