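test_that("well-separated mixtures are recovered near the generative truth", {
  n <- 200
  # components constructed with exact moments so the check isolates the
  # estimator from sampling noise of the generative draw
  x <- c(exact_moments(n / 2, 10, 1, seed = 41),
         exact_moments(n / 2, 0, 1, seed = 141))
  group <- rep(c("T2DM", "HC"), n / 2)   # both groups span both components
  fit <- fit_abnormality_model(x, group)
  expect_lt(abs(fit$mu_n - 0), 0.1)
  expect_lt(abs(fit$mu_a - 10), 0.1)
  expect_lt(abs(fit$w_a - 0.5), 0.05)
  # log-likelihood trace is non-decreasing
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("a biomarker with no group signal collapses to a small abnormal weight", {
  set.seed(42)
  x <- rnorm(120)
  group <- rep(c("T2DM", "HC"), 60)
  fit <- fit_abnormality_model(x, group)
  expect_lt(fit$w_a, 0.5)
  # posteriors stay unconfident across the observed range
  p <- posterior_abnormality(fit, x)
  expect_lt(mean(p), 0.5)
})

test_that("mixture fitting enforces its preconditions", {
  expect_error(fit_abnormality_model(rnorm(12), rep(c("T2DM", "HC"),
                                                    c(9, 3))),
               "10 subjects")
  expect_error(fit_abnormality_model(c(rnorm(10), rep(1, 10)),
                                     rep(c("T2DM", "HC"), each = 10)),
               "constant")
})

test_that("posterior abnormality follows the equal-variance logistic form", {
  m <- list(mu_n = 0, sd_n = 1, mu_a = 2, sd_a = 1, w_a = 0.5)
  # 1 / (1 + exp(-2 x + 2)) at x = 1.5
  expect_equal(posterior_abnormality(m, 1.5), 1 / (1 + exp(-1)),
               tolerance = 1e-10)
  expect_equal(posterior_abnormality(m, 1), 0.5)       # equal-density point
  expect_equal(posterior_abnormality(m, 1e3), 1)       # x -> +Inf
  expect_equal(posterior_abnormality(m, -1e3), 0)      # x -> -Inf
  # monotone non-decreasing in x for equal sds
  xs <- seq(-6, 6, length.out = 200)
  expect_true(all(diff(posterior_abnormality(m, xs)) >= 0))
})

test_that("severity quantization maps to the 4-level scale with ties up", {
  expect_equal(quantize_severity(0), 0)
  expect_equal(quantize_severity(0.5), 2 / 3)     # tie rounds up
  expect_equal(quantize_severity(0.30), 1 / 3)
  expect_equal(quantize_severity(1), 1)
  expect_equal(quantize_severity(c(1 / 6, 5 / 6)), c(1 / 3, 1))
  expect_error(quantize_severity(1.2), "0,1")
})

test_that("probabilistic Kendall distance scores discordant pairs by confidence", {
  expect_equal(prob_kendall_distance(1:3, c(0.9, 0.6, 0.2)), 0)
  expect_equal(prob_kendall_distance(1:3, c(0.2, 0.6, 0.9)), 1.4)
  expect_equal(prob_kendall_distance(1:3, rep(0.4, 3)), 0)  # ties cost nothing
  expect_error(prob_kendall_distance(1:3, c(0.1, 0.2)), "length")
  # reduces to the classic Kendall distance for 0/1 posteriors
  expect_equal(prob_kendall_distance(1:4, c(0, 1, 0, 1)), 3)
})

test_that("central ordering is exact for shared posteriors", {
  P <- matrix(rep(c(0.9, 0.5, 0.1), each = 20), nrow = 20)
  sq <- central_ordering(P)
  expect_equal(sq$ordering, 1:3)
  expect_equal(sq$total_distance, 0)
  expect_error(central_ordering(P, patients = rep(FALSE, 20)), "patient")
})

test_that("the local-search ordering matches brute force on random fixtures", {
  set.seed(43)
  for (i in 1:5) {
    K <- sample(3:5, 1)
    P <- matrix(runif(50 * K), 50, K)
    bf <- brute_force_ordering(P)
    exact <- central_ordering(P)                          # exhaustive branch
    heur <- central_ordering(P, exhaustive_limit = 1)     # local search
    expect_equal(exact$total_distance, bf$objective, tolerance = 1e-9)
    expect_equal(heur$total_distance, bf$objective, tolerance = 1e-9)
  }
})

test_that("reversing all posteriors reverses the optimal ordering", {
  set.seed(44)
  P <- matrix(runif(200), 40, 5)
  a <- central_ordering(P)
  b <- central_ordering(1 - P)
  expect_equal(b$ordering, rev(a$ordering))
})

test_that("event centers follow the rank formula and stay sorted in [0,1]", {
  P <- matrix(c(1.0, 0.5, 0.0), nrow = 1)
  expect_equal(estimate_event_centers(1:3, P), c(1, 3, 5) / 6)
  # identical subjects reproduce the single-subject value
  P10 <- P[rep(1, 10), ]
  expect_equal(estimate_event_centers(1:3, P10), c(1, 3, 5) / 6)
  # arbitrary input: sorted, within [0,1]
  set.seed(45)
  Pr <- matrix(runif(120), 30, 4)
  ec <- estimate_event_centers(c(2, 4, 1, 3), Pr)
  expect_true(all(diff(ec) >= 0))
  expect_true(all(ec >= 0 & ec <= 1))
  expect_error(estimate_event_centers(1:3, matrix(0.5, 4, 3)), "certainty")
})

test_that("a single bootstrap resample yields a permutation matrix", {
  co <- generate_cohort(noise_free_spec(K = 4, seed = 46))
  proc <- processed_biomarkers(co)
  set.seed(46)
  pv <- bootstrap_sequence(proc, co$covariates$group, B = 1,
                           method = "marginal")
  expect_true(all(pv$F %in% c(0, 1)))
  expect_equal(rowSums(pv$F), setNames(rep(1, 4), rownames(pv$F)))
  expect_equal(unname(colSums(pv$F)), rep(1, 4))
})

test_that("bootstrap on a noise-free staged cohort concentrates on the truth", {
  co <- generate_cohort(noise_free_spec(K = 5, seed = 47))
  proc <- processed_biomarkers(co)
  set.seed(47)
  pv <- bootstrap_sequence(proc, co$covariates$group, B = 20)
  expect_equal(unname(pv$F), diag(5))     # identity permutation every time
  expect_true(all(abs(rowSums(pv$F) - 1) < 1e-9))
  expect_true(all(abs(colSums(pv$F) - 1) < 1e-9))
  expect_equal(unname(pv$modal_position), 1:5)
  expect_error(bootstrap_sequence(proc, co$covariates$group, B = 0), "B must")
})

test_that("the stage-coupled fit recovers a strongly separated cascade", {
  co <- generate_cohort(noise_free_spec(K = 6, n_patients = 80,
                                        n_controls = 50, seed = 48))
  proc <- processed_biomarkers(co)
  set.seed(48)
  fit <- suppressWarnings(fit_ebm(proc, co$covariates$group))
  expect_equal(fit$sequence$ordering, 1:6)
  expect_gt(cor(fit$staging$assignment$mean_stage, co$ground_truth$stages),
            0.98)
})
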