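#' Stage likelihood of one subject under a fitted sequence
#'
#' Likelihood that a subject sits at stage k of the event sequence: events at
#' ordering positions `<= k` contribute their abnormal-component density,
#' later positions their normal-component density:
#' `L(k) = prod_{m<=k} f_a(x_sigma(m)) * prod_{m>k} f_n(x_sigma(m))`.
#' Strictly positive for finite values; computed in log space.
#'
#' @param x Subject's biomarker vector (length K, model column order).
#' @param sequence An `event_sequence` (or bare ordering permutation).
#' @param model An `abnormality_model` for the same K biomarkers.
#' @param k Stage in `0:K`, or `NULL` for all stages at once.
#' @param log Return log-likelihood (default `FALSE`).
#' @return Likelihood value(s); a vector of length K+1 when `k` is `NULL`.
#' @export
stage_likelihood <- function(x, sequence, model, k = NULL, log = FALSE) {
  ordering <- if (inherits(sequence, "event_sequence")) sequence$ordering
              else as.integer(sequence)
  K <- length(ordering)
  if (length(x) != K) stop("x must have one value per biomarker")
  la <- vapply(seq_len(K), function(m) {
    f <- model[[ordering[m]]]
    stats::dnorm(x[ordering[m]], f$mu_a, f$sd_a, log = TRUE)
  }, numeric(1))
  ln <- vapply(seq_len(K), function(m) {
    f <- model[[ordering[m]]]
    stats::dnorm(x[ordering[m]], f$mu_n, f$sd_n, log = TRUE)
  }, numeric(1))
  # loglik(k) = sum of la over positions <= k plus ln over positions > k
  ll <- c(0, cumsum(la)) + rev(c(0, cumsum(rev(ln))))
  if (!is.null(k)) {
    if (any(k < 0 | k > K)) stop("k must lie in 0..K")
    ll <- ll[k + 1]
  }
  if (log) ll else exp(ll)
}

# per-column component log-densities: list of n x K matrices LA (abnormal)
# and LN (normal)
component_loglik <- function(values, model) {
  values <- as.matrix(values)
  K <- ncol(values)
  LA <- matrix(0, nrow(values), K)
  LN <- matrix(0, nrow(values), K)
  for (j in seq_len(K)) {
    f <- model[[j]]
    LA[, j] <- stats::dnorm(values[, j], f$mu_a, f$sd_a, log = TRUE)
    LN[, j] <- stats::dnorm(values[, j], f$mu_n, f$sd_n, log = TRUE)
  }
  list(LA = LA, LN = LN)
}

# n x (K+1) stage log-likelihoods from component log-densities:
# ll_k = sum_{m<=k} LA[,sigma(m)] + sum_{m>k} LN[,sigma(m)], via cumulative
# sums expressed as triangular matrix products (no per-row loops)
stage_ll_from_components <- function(LA, LN, ordering) {
  K <- length(ordering)
  U <- upper.tri(matrix(0, K, K), diag = TRUE) * 1
  A <- LA[, ordering, drop = FALSE]
  N <- LN[, ordering, drop = FALSE]
  CA <- A %*% U          # CA[, k] = sum_{m<=k} A[, m]
  CN <- N %*% U
  TN <- CN[, K]
  out <- cbind(TN, CA + (TN - CN))
  dimnames(out) <- NULL
  out
}

# n x (K+1) matrix of per-subject stage log-likelihoods
stage_loglik_matrix <- function(values, sequence, model) {
  ordering <- if (inherits(sequence, "event_sequence")) sequence$ordering
              else as.integer(sequence)
  cl <- component_loglik(as.matrix(values), model)
  stage_ll_from_components(cl$LA, cl$LN, ordering)
}

#' Posterior distribution over stages for each subject
#'
#' Combines stage likelihoods with a prior over stages:
#' `P(stage = k | x) \propto pi_k L(k)`, computed in log space so that deeply
#' abnormal or deeply normal profiles do not underflow.
#'
#' @param values Subjects x K biomarker matrix.
#' @param sequence An `event_sequence` or ordering.
#' @param model An `abnormality_model`.
#' @param prior Prior probabilities over stages `0:K` (default uniform).
#' @return Subjects x (K+1) matrix; rows sum to 1.
#' @export
stage_posterior <- function(values, sequence, model, prior = NULL) {
  ll <- stage_loglik_matrix(values, sequence, model)
  Kp1 <- ncol(ll)
  if (is.null(prior)) prior <- rep(1 / Kp1, Kp1)
  if (length(prior) != Kp1 || any(prior < 0))
    stop("prior must be a non-negative vector over stages 0..K")
  if (sum(prior) <= 0) stop("prior must have positive mass")
  prior <- prior / sum(prior)
  lp <- sweep(ll, 2, log(prior), "+")
  lp[, prior == 0] <- -Inf
  mx <- apply(lp, 1, max)
  if (any(!is.finite(mx))) stop("all stage log-likelihoods are -Inf")
  w <- exp(lp - mx)
  w / rowSums(w)
}

#' EM refinement of the stage prior and final stage assignment
#'
#' Holding the event sequence and mixture models fixed, alternates an E-step
#' (stage posteriors under the current prior) with an M-step (prior = mean
#' posterior mass per stage) until the prior changes by less than `tol` in
#' the max norm. The total log-likelihood is non-decreasing across
#' iterations. Assignments report the MAP stage (ties to the smallest
#' stage), the posterior-mean stage, and the mean stage normalized by K.
#'
#' @param values Subjects x K biomarker matrix.
#' @param sequence An `event_sequence` or ordering.
#' @param model An `abnormality_model`.
#' @param max_iter,tol Convergence controls.
#' @return Object of class `stage_assignment`: `prior`, `posterior`
#'   (subjects x K+1), `assignment` (data.frame: `map_stage`, `mean_stage`,
#'   `normalized_stage`), `loglik_trace`, `converged`.
#' @export
em_refine <- function(values, sequence, model, max_iter = 1000, tol = 1e-6) {
  ll <- stage_loglik_matrix(values, sequence, model)
  Kp1 <- ncol(ll)
  K <- Kp1 - 1L
  prior <- rep(1 / Kp1, Kp1)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lp <- sweep(ll, 2, log(prior), "+")
    mx <- apply(lp, 1, max)
    w <- exp(lp - mx)
    rs <- rowSums(w)
    trace <- c(trace, sum(mx + log(rs)))
    post <- w / rs
    prior_new <- colMeans(post)
    if (max(abs(prior_new - prior)) < tol) {
      prior <- prior_new
      converged <- TRUE
      break
    }
    prior <- prior_new
  }
  if (!converged)
    warning("stage EM did not converge within ", max_iter, " iterations")
  post <- stage_posterior(values, sequence, model, prior)
  mean_stage <- drop(post %*% (0:K))
  assignment <- data.frame(
    map_stage = apply(post, 1, which.max) - 1L,  # first max = smallest stage
    mean_stage = mean_stage,
    normalized_stage = mean_stage / K
  )
  structure(list(prior = prior, posterior = post, assignment = assignment,
                 loglik_trace = trace, converged = converged),
            class = "stage_assignment")
}

#' Normalized disease stage in [0,1]
#'
#' Posterior-mean stage divided by the number of events K, giving the
#' continuous severity index used in group comparisons.
#'
#' @param x A `stage_assignment`, or a stage-posterior matrix/vector over
#'   stages `0:K`.
#' @return Numeric vector of values in `[0,1]`.
#' @export
normalized_stage <- function(x) {
  if (inherits(x, "stage_assignment")) return(x$assignment$normalized_stage)
  p <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  K <- ncol(p) - 1L
  if (K < 1) stop("need K >= 1")
  drop(p %*% (0:K)) / K
}
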