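# shared fixtures, all generated in code

# cohort with strong component separation and stages pinned to cover 0..K,
# i.e. the "noise-free, perfectly staged" regime where the sequence is
# exactly identified
noise_free_spec <- function(K = 5, n_patients = 60, n_controls = 40,
                            seed = 101) {
  n <- n_patients + n_controls
  cohort_spec(
    n_patients = n_patients, n_controls = n_controls, K = K,
    mu_abnormal = 8, sd_normal = 0.3, sd_abnormal = 0.3,
    sequence = seq_len(K), stages = rep(0:K, length.out = n),
    covariate_effects = c(age = 0, sex = 0, education = 0), seed = seed)
}

covariates_of <- function(cohort) {
  cohort$covariates[, c("age", "sex", "education")]
}

processed_biomarkers <- function(cohort) {
  preprocess_biomarkers(cohort$biomarkers, covariates_of(cohort),
                        cohort$covariates$group, cohort$manifest)
}

# sample with exact mean and sd (n-1 denominator)
exact_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  drop(scale(x)) * sd + mean
}

# independent brute-force minimiser of the total probabilistic Kendall
# distance (enumerates all K! orderings, summing prob_kendall_distance
# over subjects)
brute_force_ordering <- function(P) {
  K <- ncol(P)
  perms <- expand_permutations(K)
  objs <- apply(perms, 1, function(o)
    sum(apply(P, 1, function(p) prob_kendall_distance(o, p))))
  list(ordering = perms[which.min(objs), ], objective = min(objs))
}

expand_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- expand_permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(first) {
    rest <- setdiff(seq_len(K), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

# Kendall tau-b between two orderings (as permutations, earliest first)
ordering_tau <- function(a, b) {
  K <- length(a)
  stats::cor(match(seq_len(K), a), match(seq_len(K), b), method = "kendall")
}
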