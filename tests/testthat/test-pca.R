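equicorrelation <- function(p, r) {
  R <- matrix(r, p, p)
  diag(R) <- 1
  R
}

test_that("KMO matches the equicorrelation closed form", {
  r <- 0.5
  # partial correlations are r/(1 + r) for p = 3, so
  # KMO = (1 + r)^2 / ((1 + r)^2 + 1)
  expected <- (1 + r)^2 / ((1 + r)^2 + 1)
  got <- kmo(equicorrelation(3, r))
  expect_equal(got$kmo_overall, expected, tolerance = 1e-10)
  expect_equal(got$kmo_per_item, rep(expected, 3), tolerance = 1e-10)
})

test_that("KMO rejects degenerate or malformed inputs", {
  expect_error(kmo(diag(3)), "identity")
  M <- equicorrelation(3, 0.4); M[1, 2] <- 0.9
  expect_error(kmo(M), "symmetric")
  D <- equicorrelation(3, 0.4); diag(D) <- 2
  expect_error(kmo(D), "unit diagonal")
})

test_that("KMO and Bartlett are invariant to item reordering", {
  set.seed(31)
  X <- matrix(rnorm(300), 100, 3) %*% matrix(c(1, .5, .2, 0, 1, .4, 0, 0, 1),
                                             3, 3)
  R <- cor(X)
  perm <- c(3, 1, 2)
  expect_equal(kmo(R)$kmo_overall, kmo(R[perm, perm])$kmo_overall,
               tolerance = 1e-12)
  expect_equal(bartlett_sphericity(R, 100)$chi2,
               bartlett_sphericity(R[perm, perm], 100)$chi2,
               tolerance = 1e-12)
})

test_that("Bartlett sphericity matches its closed form and limits", {
  idd <- bartlett_sphericity(diag(4), 30)
  expect_equal(idd$chi2, 0)
  expect_equal(idd$p_value, 1)
  # p = 2, r = 0.5, n = 50: chi2 = -(49 - 1.5) log(0.75)
  got <- bartlett_sphericity(equicorrelation(2, 0.5), 50)
  expect_equal(got$chi2, -(49 - 1.5) * log(0.75), tolerance = 1e-12)
  expect_equal(got$chi2, 13.665, tolerance = 1e-3)
  expect_equal(got$df, 1L)
  # chi2 strictly increases in |r| at fixed n, p = 2
  chis <- vapply(c(0.1, 0.3, 0.5, 0.7),
                 function(r) bartlett_sphericity(equicorrelation(2, r),
                                                 50)$chi2, numeric(1))
  expect_true(all(diff(chis) > 0))
  expect_error(bartlett_sphericity(equicorrelation(2, 0.5), 2), "n > p")
})

test_that("two-item PCA has eigenvalues 1 + r and 1 - r", {
  set.seed(32)
  z <- matrix(rnorm(1000), 500, 2)
  z[, 2] <- 0.6 * z[, 1] + sqrt(1 - 0.36) * z[, 2]
  model <- suppressWarnings(fit_pca(z))
  r <- cor(z)[1, 2]
  expect_equal(model$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-10)
  expect_equal(model$explained_fraction, c(1 + r, 1 - r) / 2,
               tolerance = 1e-10)
})

test_that("PCA model satisfies its structural invariants", {
  set.seed(33)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% diag(6) +
    matrix(rnorm(200), 200, 1)[, rep(1, 6)] * 0.8
  colnames(X) <- paste0("it", 1:6)
  model <- suppressWarnings(fit_pca(X))
  expect_equal(sum(model$explained_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  expect_equal(sum(model$eigenvalues), 6, tolerance = 1e-8)
  # scores of distinct components are uncorrelated
  cc <- cor(model$scores)
  expect_equal(max(abs(cc[upper.tri(cc)])), 0, tolerance = 1e-8)
  # sign convention: largest |loading| entry positive
  for (j in 1:6) {
    v <- model$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  X2 <- X; X2[, 3] <- 5
  expect_error(fit_pca(X2), "it3")
})

test_that("uncorrelated items give near-unit eigenvalues", {
  set.seed(34)
  model <- suppressWarnings(fit_pca(matrix(rnorm(500 * 5), 500, 5)))
  expect_true(all(abs(model$eigenvalues - 1) < 0.25))
  expect_equal(model$n_selected, sum(model$eigenvalues > 1))
})

test_that("component selection reproduces the published eigenvalue counts", {
  fake_model <- function(ev, p) {
    ev <- c(ev, rep((p - sum(ev)) / (p - length(ev)), p - length(ev)))
    structure(list(eigenvalues = ev, explained_fraction = ev / p),
              class = "pca_model")
  }
  cvlt <- fake_model(c(8.19, 2.47, 1.95, 1.03), 18)
  expect_equal(select_components(cvlt, "kaiser", quiet = TRUE), 4L)
  stroop <- fake_model(c(7.67, 1.84), 11)
  expect_equal(select_components(stroop, "kaiser", quiet = TRUE), 2L)
  wcst <- fake_model(c(10.30, 2.64, 1.88, 1.35), 18)
  expect_equal(select_components(wcst, "kaiser", quiet = TRUE), 4L)
})

test_that("the jolliffe rule needs 70% cumulative variance and 0.7 eigenvalues", {
  m <- structure(list(eigenvalues = c(2.0, 1.1, 0.5, 0.4),
                      explained_fraction = c(2.0, 1.1, 0.5, 0.4) / 4),
                 class = "pca_model")
  # cumulative: .5, .775 -> m = 2, both eigenvalues > 0.7
  expect_equal(select_components(m, "jolliffe", quiet = TRUE), 2L)
  flat <- structure(list(eigenvalues = rep(1, 4) - 1e-12,
                         explained_fraction = rep(0.25, 4)),
                    class = "pca_model")
  expect_equal(select_components(flat, "kaiser", quiet = TRUE), 0L)
  expect_equal(select_components(flat, "jolliffe", quiet = TRUE), 3L)
})

test_that("composite scores weight selected components by eigenvalue", {
  m <- structure(list(eigenvalues = c(1.6, 0.4),
                      explained_fraction = c(0.8, 0.2),
                      scores = cbind(c(1, 0), c(-1, 2)), n_selected = 2L),
                 class = "pca_model")
  expect_equal(composite_score(m)[1], (1.6 * 1 + 0.4 * -1) / 2)  # 0.6
  expect_equal(composite_score(m, "equal"), c(0, 1))
  m1 <- m; m1$n_selected <- 1L
  expect_equal(composite_score(m1), m$scores[, 1])  # single component
  m$eigenvalues <- c(1.2, 1.2)
  expect_equal(composite_score(m), rowMeans(m$scores))  # equal eigenvalues
  m0 <- m; m0$n_selected <- 0L
  expect_error(composite_score(m0), "no components")
})

test_that("noise-free factor batteries recover the planted factor count", {
  set.seed(35)
  for (f in c(2L, 3L)) {
    battery <- list(n_items = 3L * f, n_factors = f, blocks = rep(3L, f),
                    loading = 0.9, noise_sd = 0.05)
    items <- generate_battery_items(battery,
                                    matrix(rnorm(400 * f), 400, f))
    model <- suppressWarnings(fit_pca(items))
    expect_equal(model$n_selected, f)
  }
})
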