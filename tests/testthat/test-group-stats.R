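test_that("irrelevant orthogonal covariates leave the group contrast intact", {
  set.seed(61)
  n <- 60
  group <- rep(c("A", "B"), each = n / 2)
  cov <- data.frame(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 12, 3))
  y <- rnorm(n) + (group == "B")
  # orthogonalize covariates against intercept, group and outcome: they then
  # absorb no variance, so the group sum of squares and residual sum of
  # squares match one-way ANOVA and the F statistics differ only by the
  # residual degrees of freedom
  g <- as.numeric(group == "B")
  for (v in names(cov)) cov[[v]] <- resid(lm(cov[[v]] ~ g + y))
  res <- ancova_compare(y, group, cov)
  f_oneway <- summary(aov(y ~ group))[[1]]$`F value`[1]
  expect_equal(res$F, f_oneway * (n - 2 - 3) / (n - 2), tolerance = 1e-8)
  # adjusted means at covariate means equal the raw group means here
  expect_equal(res$adj_mean_A, mean(y[group == "A"]), tolerance = 1e-8)
  expect_equal(res$adj_mean_B, mean(y[group == "B"]), tolerance = 1e-8)
})

test_that("identical groups give a null ANCOVA result", {
  set.seed(62)
  y <- rep(rnorm(30), 2)
  group <- rep(c("A", "B"), each = 30)
  cov <- data.frame(age = rep(rnorm(30, 55, 5), 2),
                    sex = rep(rbinom(30, 1, 0.5), 2),
                    education = rep(rnorm(30, 12, 2), 2))
  res <- ancova_compare(y, group, cov)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_equal(res$adj_mean_A, res$adj_mean_B, tolerance = 1e-10)
})

test_that("ANCOVA matches the explicit projection oracle on a printed fixture", {
  y <- c(3.1, 2.4, 4.0, 3.3, 5.2, 4.8, 6.1, 5.5)
  group <- rep(c("HC", "T2DM"), each = 4)
  cov <- data.frame(age = c(48, 51, 60, 55, 62, 49, 58, 53),
                    sex = c(0, 1, 0, 1, 1, 0, 1, 0),
                    education = c(12, 10, 16, 13, 9, 15, 11, 14))
  res <- ancova_compare(y, group, cov)
  # oracle: residual sums of squares from explicit least-squares solves
  X_full <- cbind(1, group == "T2DM", as.matrix(cov))
  X_red <- cbind(1, as.matrix(cov))
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  F_oracle <- ((rss(X_red) - rss(X_full)) / 1) / (rss(X_full) / (8 - 5))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$df2, 3)
})

test_that("pooled t-test matches its closed form and stats::t.test", {
  a <- exact_moments(100, 1, 1, seed = 63)
  b <- exact_moments(100, 0, 1, seed = 64)
  res <- two_sample_t(a, b)
  expect_equal(res$t, 1 / sqrt(2 / 100), tolerance = 1e-10)  # 7.0711
  expect_equal(res$df, 198L)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # antisymmetry
  swapped <- two_sample_t(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # degenerate cases
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$t, 0)
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p, 1)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("the sex contingency table reproduces the published chi-square", {
  tab <- matrix(c(87, 50, 32, 37), 2)   # males / females by group
  res <- chi_square_2x2(tab)
  expect_equal(round(res$chi2, 3), 5.517)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 0.05)
  # agrees with the uncorrected Pearson test
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("chi-square is zero for proportional tables and symmetric to transpose", {
  expect_equal(chi_square_2x2(matrix(c(20, 40, 10, 20), 2))$chi2, 0)
  tab <- matrix(c(12, 30, 25, 9), 2)
  expect_equal(chi_square_2x2(tab)$chi2, chi_square_2x2(t(tab))$chi2)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_2x2(matrix(1:6, 2)), "2x2")
})

test_that("partial correlation reduces to Pearson and handles exact dependence", {
  set.seed(65)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  res <- partial_correlation(x, y)
  expect_equal(res$r, cor(x, y), tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  cov <- data.frame(z = rnorm(40))
  expect_equal(partial_correlation(x, x + 0 * cov$z, cov)$r, 1,
               tolerance = 1e-10)
  expect_error(partial_correlation(x, rep(1, 40), cov), "constant")
  expect_error(partial_correlation(1:3, 1:3, data.frame(a = 1:3, b = 4:6)),
               "n >")
})

test_that("partial correlation equals the residualize-then-correlate oracle", {
  x <- c(2.3, 1.1, 4.2, 3.0, 5.1, 2.8)
  y <- c(7.1, 5.2, 9.8, 8.1, 11.9, 6.4)
  z <- data.frame(age = c(50, 47, 63, 55, 68, 52))
  res <- partial_correlation(x, y, z)
  rx <- resid(lm(x ~ age, data = z))
  ry <- resid(lm(y ~ age, data = z))
  expect_equal(res$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(res$df, 6L - 1L - 2L)
  # p from the t transform
  t_stat <- res$r * sqrt(res$df / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(t_stat), res$df), tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0,1")
  # manual step-up on an unsorted vector
  p <- c(0.03, 0.005, 0.8, 0.01)
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(bh_fdr(p)[o], pmin(q_sorted, 1), tolerance = 1e-12)
  # adjusted values never fall below the raw ones
  expect_true(all(bh_fdr(p) >= p))
})

test_that("outcome tables and correlation grids form single FDR families", {
  set.seed(66)
  n <- 80
  group <- rep(c("T2DM", "HC"), each = n / 2)
  cov <- data.frame(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 12, 3))
  out <- data.frame(a = rnorm(n) - 0.8 * (group == "T2DM"), b = rnorm(n))
  res <- compare_outcomes(out, group, cov)
  expect_equal(res$p_fdr, bh_fdr(res$p))
  expect_true(all(res$p_fdr >= res$p))
  grid <- correlation_grid(out, data.frame(GLU = rnorm(n), FBG = rnorm(n)),
                           cov)
  expect_equal(nrow(grid), 4)
  expect_equal(grid$p_fdr, bh_fdr(grid$p))
  expect_true(all(abs(grid$r) <= 1))
})
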