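#' Fit a normal/abnormal Gaussian mixture to one biomarker
#'
#' Two-component Gaussian mixture fitted by expectation-maximisation on all
#' subjects, discerning the "normal" (pre-event) and "abnormal" (post-event)
#' distributions of a harmonized biomarker (higher = worse) without any
#' manual outlier definition. The EM is restarted from several
#' quantile-split initializations spanning small to large abnormal fractions,
#' plus one initialization at the control group's moments; after
#' convergence, components are relabelled so that `mu_a > mu_n`. The best
#' log-likelihood wins, unless the two-component model fails to beat a
#' single Gaussian by the BIC margin for its three extra parameters — in
#' that case the data carry no real evidence of a second component, every
#' split of the bulk is an artefact, and the restart with the smallest
#' abnormal weight is returned instead, so a biomarker with no signal
#' collapses towards "mostly normal" rather than an arbitrary split. The
#' recorded log-likelihood trace is non-decreasing.
#'
#' @param values Harmonized biomarker values, all subjects.
#' @param group Group labels aligned with `values`.
#' @param control_label Label of the control group (default `"HC"`).
#' @param n_restarts Number of quantile-split initializations (default 5).
#' @param max_iter,tol EM iteration controls.
#' @param evidence_threshold Log-likelihood gain over the single-Gaussian
#'   fit required to trust the maximum-likelihood mixture; default is the
#'   BIC penalty `1.5 * log(n)` for the three extra parameters.
#' @return List: `mu_n`, `sd_n`, `mu_a`, `sd_a`, `w_a` (abnormal mixing
#'   weight), `loglik`, `trace` (per-iteration log-likelihoods of the chosen
#'   restart).
#' @export
fit_abnormality_model <- function(values, group, control_label = "HC",
                                  n_restarts = 5, max_iter = 500,
                                  tol = 1e-6, evidence_threshold = NULL) {
  x <- as.numeric(values)
  ctl <- x[group == control_label]
  pat <- x[group != control_label]
  if (length(ctl) < 10 || length(pat) < 10)
    stop("need at least 10 subjects per group")
  mu_c <- mean(ctl); sd_c <- stats::sd(ctl)
  if (sd_c == 0) stop("control values are constant")
  sd_floor <- max(1e-3 * stats::sd(x), 1e-8)

  run_em <- function(mu_n, sd_n, mu_a, sd_a, w) {
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      da <- stats::dnorm(x, mu_a, sd_a)
      dn <- stats::dnorm(x, mu_n, sd_n)
      mix <- w * da + (1 - w) * dn
      mix[mix < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- sum(log(mix))
      if (ll < ll_old - 1e-10) break
      trace <- c(trace, ll)
      if (it > 1 && ll - ll_old < tol) { ll_old <- ll; break }
      ll_old <- ll
      g <- w * da / mix
      sw <- sum(g)
      if (sw < 1e-6 || length(x) - sw < 1e-6) break
      mu_a <- sum(g * x) / sw
      sd_a <- max(sqrt(sum(g * (x - mu_a)^2) / sw), sd_floor)
      mu_n <- sum((1 - g) * x) / (length(x) - sw)
      sd_n <- max(sqrt(sum((1 - g) * (x - mu_n)^2) / (length(x) - sw)),
                  sd_floor)
      w <- min(max(sw / length(x), 1e-4), 1 - 1e-4)
    }
    if (mu_a < mu_n) {  # relabel: abnormal is the upper component
      tmp <- c(mu_n, sd_n); mu_n <- mu_a; sd_n <- sd_a
      mu_a <- tmp[1]; sd_a <- tmp[2]; w <- 1 - w
    }
    list(mu_n = mu_n, sd_n = sd_n, mu_a = mu_a, sd_a = sd_a, w_a = w,
         loglik = ll_old, trace = trace)
  }

  # quantile-split starts: lower 1-w0 of the sample seeds the normal
  # component, upper w0 the abnormal one
  w_grid <- seq(0.1, 0.9, length.out = n_restarts)
  fits <- lapply(w_grid, function(w0) {
    cut <- stats::quantile(x, 1 - w0, names = FALSE)
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (length(lo) < 2 || length(hi) < 2) return(NULL)
    run_em(mean(lo), max(stats::sd(lo), sd_floor),
           mean(hi), max(stats::sd(hi), sd_floor), w0)
  })
  fits <- c(fits, list(run_em(mu_c, sd_c, mean(pat) + stats::sd(pat),
                              stats::sd(pat), 0.3)))
  fits <- Filter(function(f) !is.null(f) && is.finite(f$loglik) &&
                   f$mu_a > f$mu_n, fits)
  if (!length(fits))
    stop("EM could not satisfy mu_abnormal > mu_normal; inspect this ",
         "biomarker's direction and distribution")
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  n <- length(x)
  ll_single <- sum(stats::dnorm(x, mean(x),
                                stats::sd(x) * sqrt((n - 1) / n), log = TRUE))
  if (is.null(evidence_threshold)) evidence_threshold <- 1.5 * log(n)
  if (max(lls) - ll_single >= evidence_threshold) {
    fits[[which.max(lls)]]
  } else {
    # no real second component: return the canonical "mostly normal" fit
    # (bulk as the normal component, a vestigial abnormal tail) instead of
    # an arbitrary split of the bulk
    mu_n <- mean(x); sd_n <- stats::sd(x) * sqrt((n - 1) / n)
    null_fit <- list(mu_n = mu_n, sd_n = sd_n, mu_a = mu_n + 2 * sd_n,
                     sd_a = sd_n, w_a = 0.05)
    d <- 0.05 * stats::dnorm(x, null_fit$mu_a, sd_n) +
      0.95 * stats::dnorm(x, mu_n, sd_n)
    null_fit$loglik <- sum(log(pmax(d, .Machine$double.xmin)))
    null_fit$trace <- null_fit$loglik
    null_fit
  }
}

#' Fit abnormality mixtures for every biomarker column
#'
#' @param values Matrix of harmonized biomarker values (subjects x K).
#' @param group Group labels.
#' @param ... Passed to [fit_abnormality_model()].
#' @return Object of class `abnormality_model`: list of per-biomarker fits,
#'   named by column.
#' @export
fit_abnormality_models <- function(values, group, ...) {
  values <- as.matrix(values)
  fits <- lapply(seq_len(ncol(values)), function(j)
    fit_abnormality_model(values[, j], group, ...))
  names(fits) <- colnames(values)
  structure(fits, class = "abnormality_model")
}

#' Posterior probability that an event has occurred
#'
#' Bayes posterior under the fitted mixture:
#' `P(event | x) = w_a f_a(x) / (w_a f_a(x) + (1 - w_a) f_n(x))`.
#' For equal component sds this is a logistic function of `x`, monotone
#' non-decreasing in the harmonized value.
#'
#' @param model One biomarker's fit from [fit_abnormality_model()], or an
#'   `abnormality_model` when `x` is a matrix.
#' @param x Value(s); a subjects x K matrix when `model` is the full panel.
#' @return Posterior probabilities in `[0,1]`, same shape as `x`.
#' @export
posterior_abnormality <- function(model, x) {
  if (inherits(model, "abnormality_model")) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == length(model))
    out <- vapply(seq_along(model), function(j)
      posterior_abnormality(model[[j]], x[, j]), numeric(nrow(x)))
    out <- matrix(out, nrow = nrow(x))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  # log-space for numerical stability in the far tails
  la <- stats::dnorm(x, model$mu_a, model$sd_a, log = TRUE) + log(model$w_a)
  ln <- stats::dnorm(x, model$mu_n, model$sd_n, log = TRUE) + log(1 - model$w_a)
  1 / (1 + exp(ln - la))
}

#' Quantize an abnormality probability to the 4-level severity scale
#'
#' Maps a posterior probability to the nearest of
#' {0 (none), 1/3 (mild), 2/3 (moderate), 1 (severe)}; ties round up.
#' Reporting convenience only — sequence fitting uses the continuous
#' posteriors.
#'
#' @param p Probabilities in `[0,1]`.
#' @return Values in `{0, 1/3, 2/3, 1}`.
#' @export
quantize_severity <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0,1]")
  levels <- c(0, 1 / 3, 2 / 3, 1)
  mids <- c(1 / 6, 1 / 2, 5 / 6)
  levels[findInterval(p, mids) + 1L]
}

#' Probabilistic Kendall-tau distance between an ordering and a subject
#'
#' For each pair of events (i before j in the candidate ordering), a penalty
#' `|p_i - p_j|` accrues when the subject's posteriors are discordant with
#' the ordering (`p_j > p_i`): confident discordances cost more, and the
#' distance reduces to the classic Kendall distance for 0/1 posteriors.
#' Zero iff the subject's descending-posterior order agrees with the
#' ordering up to ties.
#'
#' @param ordering Permutation of `1:K` (position 1 = earliest event).
#' @param p Subject posterior vector of length K (entries in `[0,1]`).
#' @return Non-negative distance.
#' @export
prob_kendall_distance <- function(ordering, p) {
  K <- length(ordering)
  if (length(p) != K) stop("posterior vector length must match ordering")
  d <- 0
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    pi <- p[ordering[a]]; pj <- p[ordering[b]]
    if (pj > pi) d <- d + (pj - pi)
  }
  d
}

# Pairwise discordance matrix: D[i, j] = total cost, over subjects, of
# placing event i before event j. The ordering objective is then
# sum over ordered pairs of D, which makes both exhaustive search and local
# search O(K^2) per candidate after one O(n K^2) precomputation.
pairwise_discordance <- function(P) {
  K <- ncol(P)
  D <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j) D[i, j] <- sum(pmax(P[, j] - P[, i], 0))
  }
  D
}

ordering_objective <- function(ordering, D) {
  K <- length(ordering)
  s <- 0
  for (a in seq_len(K - 1))
    s <- s + sum(D[ordering[a], ordering[(a + 1):K]])
  s
}

# All permutations of 1:K in lexicographic order (small K only).
.all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(K - 1L)
  out <- matrix(0L, 0, K)
  for (first in seq_len(K)) {
    rest <- setdiff(seq_len(K), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Estimate the central event ordering
#'
#' Finds the permutation of biomarkers minimising the total probabilistic
#' Kendall-tau distance to the patients' posterior vectors (the mean
#' spatiotemporal cascade). For `K <= exhaustive_limit` the global minimiser
#' is found by exhaustive search over all K! permutations (ties broken by
#' lexicographically smallest permutation); for larger K, the ordering is
#' initialized by descending mean posterior and refined by
#' adjacent-swap and single-element-insertion local search until no move
#' improves the objective.
#'
#' @param posteriors Subjects x K posterior matrix.
#' @param patients Logical mask of patient rows (default all rows).
#' @param exhaustive_limit Largest K solved exhaustively (default 7).
#' @return Object of class `event_sequence`: `ordering` (permutation, earliest
#'   first), `event_centers` (non-decreasing, in `[0,1]`),
#'   `total_distance`, `biomarkers` (column names).
#' @export
central_ordering <- function(posteriors, patients = NULL,
                             exhaustive_limit = 7) {
  P <- as.matrix(posteriors)
  K <- ncol(P)
  if (K < 2) stop("need at least 2 biomarkers")
  if (is.null(patients)) patients <- rep(TRUE, nrow(P))
  Pp <- P[patients, , drop = FALSE]
  if (nrow(Pp) == 0) stop("no patient rows")
  D <- pairwise_discordance(Pp)

  if (K <= exhaustive_limit) {
    perms <- .all_permutations(K)
    objs <- apply(perms, 1, ordering_objective, D = D)
    best <- perms[which.min(objs), ]   # first strict min = lexicographic tie-break
    obj <- min(objs)
  } else {
    best <- order(colMeans(Pp), decreasing = TRUE)
    obj <- ordering_objective(best, D)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(K)) for (j in seq_len(K)) {
        if (i == j) next
        cand <- append(best[-i], best[i], after = j - 1)
        co <- ordering_objective(cand, D)
        if (co < obj - 1e-12) {
          best <- cand; obj <- co; improved <- TRUE
        }
      }
    }
  }
  ec <- estimate_event_centers(best, P, patients)
  structure(list(ordering = as.integer(best), event_centers = ec,
                 total_distance = obj, biomarkers = colnames(P)),
            class = "event_sequence")
}

#' Place event-centers on the normalized [0,1] timeline
#'
#' For the event at ordering position m, the event-center is the
#' certainty-weighted mean over subjects of `(rank - 0.5) / K`, where `rank`
#' is that event's position in the subject's descending-posterior order
#' (average ranks for ties) and the subject weight is the certainty
#' `c_s = mean_i |2 p_si - 1|`. The centers are then made non-decreasing
#' along the ordering by pool-adjacent-violators (isotonic regression).
#'
#' @param ordering Permutation of `1:K`, earliest event first.
#' @param posteriors Subjects x K posterior matrix.
#' @param patients Logical mask of rows to use (default all).
#' @return Numeric vector of K non-decreasing event-centers in `[0,1]`,
#'   aligned with `ordering`.
#' @export
estimate_event_centers <- function(ordering, posteriors, patients = NULL) {
  P <- as.matrix(posteriors)
  if (is.null(patients)) patients <- rep(TRUE, nrow(P))
  P <- P[patients, , drop = FALSE]
  K <- ncol(P)
  certainty <- rowMeans(abs(2 * P - 1))
  if (sum(certainty) == 0)
    stop("all subjects maximally uncertain (certainty weights are zero)")
  ranks <- matrix(t(apply(-P, 1, rank, ties.method = "average")),
                  nrow = nrow(P), ncol = K)
  ec_event <- colSums(certainty * (ranks - 0.5) / K) / sum(certainty)
  ec <- ec_event[ordering]
  ec <- stats::isoreg(seq_len(K), ec)$yf
  pmin(pmax(ec, 0), 1)
}

#' Bootstrap the event sequence and build a positional-variance matrix
#'
#' Draws `B` subject-level resamples with replacement and refits the complete
#' model on each (abnormality mixtures, posteriors, central ordering). The
#' positional-variance matrix `F[i, m]` is the fraction of bootstrap fits
#' placing biomarker i at ordering position m; since each fit contributes a
#' permutation, rows and columns each sum to 1. Resamples that lose an
#' entire group are redrawn (at most 10 attempts each).
#'
#' @param values Processed biomarker matrix (subjects x K, harmonized,
#'   covariate-adjusted).
#' @param group Group labels.
#' @param B Number of bootstrap resamples (default 100).
#' @param control_label Control group label.
#' @param exhaustive_limit Passed to [central_ordering()].
#' @param method `"coupled"` refits the stage-coupled estimator
#'   ([fit_ebm()], the pipeline's estimator) on each resample; `"marginal"`
#'   refits the per-column mixtures ([fit_abnormality_models()]) and the
#'   central ordering only.
#' @param ... Passed to the chosen fitting routine.
#' @return Object of class `positional_variance`: `F` (K x K matrix, rows =
#'   biomarkers, columns = positions), `event_centers` (B x K matrix of
#'   bootstrap centers, ordering-aligned), `modal_position` (per biomarker),
#'   `B`.
#' @export
bootstrap_sequence <- function(values, group, B = 100, control_label = "HC",
                               exhaustive_limit = 7,
                               method = c("coupled", "marginal"), ...) {
  values <- as.matrix(values)
  method <- match.arg(method)
  if (B < 1) stop("B must be >= 1")
  n <- nrow(values)
  K <- ncol(values)
  F <- matrix(0, K, K,
              dimnames = list(colnames(values), paste0("pos", seq_len(K))))
  ecs <- matrix(NA_real_, B, K)
  for (b in seq_len(B)) {
    for (attempt in seq_len(10)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(group[idx])) >= 2) break
      if (attempt == 10) stop("resampling kept losing a group after 10 tries")
      message("bootstrap resample ", b, " lost a group; redrawing")
    }
    vb <- values[idx, , drop = FALSE]
    gb <- group[idx]
    if (method == "coupled") {
      fit_b <- suppressWarnings(
        fit_ebm(vb, gb, control_label = control_label, n_starts = 2,
                exhaustive_limit = exhaustive_limit, ...))
      seq_b <- fit_b$sequence
    } else {
      fits <- fit_abnormality_models(vb, gb, control_label = control_label,
                                     ...)
      P <- posterior_abnormality(fits, vb)
      seq_b <- central_ordering(P, gb != control_label,
                                exhaustive_limit = exhaustive_limit)
    }
    F[cbind(seq_b$ordering, seq_len(K))] <- F[cbind(seq_b$ordering,
                                                    seq_len(K))] + 1
    ecs[b, ] <- seq_b$event_centers
  }
  structure(list(F = F / B, event_centers = ecs,
                 modal_position = apply(F, 1, which.max), B = B),
            class = "positional_variance")
}

# Burden-ranking changepoint initialization: rank subjects by total
# biomarker burden, then for each column pick the burden split that best
# separates a high (abnormal) from a low (normal) Gaussian. Columns where no
# split satisfies mu_a > mu_n fall back to a "mostly normal" configuration.
changepoint_init <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); K <- ncol(values)
  burden <- rank(rowMeans(values))
  fits <- lapply(seq_len(K), function(j) {
    x <- values[, j]
    best <- NULL
    for (q in seq(0.05, 0.95, by = 0.05)) {
      occ <- burden >= stats::quantile(burden, q)
      if (sum(occ) < 3 || sum(!occ) < 3) next
      mu_a <- mean(x[occ]); sd_a <- max(stats::sd(x[occ]), 1e-2)
      mu_n <- mean(x[!occ]); sd_n <- max(stats::sd(x[!occ]), 1e-2)
      if (mu_a <= mu_n) next
      ll <- sum(stats::dnorm(x[occ], mu_a, sd_a, log = TRUE)) +
        sum(stats::dnorm(x[!occ], mu_n, sd_n, log = TRUE))
      if (is.null(best) || ll > best$ll)
        best <- list(mu_n = mu_n, sd_n = sd_n, mu_a = mu_a, sd_a = sd_a,
                     w_a = mean(occ), ll = ll)
    }
    if (is.null(best))
      best <- list(mu_n = mean(x), sd_n = max(stats::sd(x), 1e-2),
                   mu_a = mean(x) + 2 * stats::sd(x),
                   sd_a = max(stats::sd(x), 1e-2), w_a = 0.01)
    best[c("mu_n", "sd_n", "mu_a", "sd_a", "w_a")]
  })
  names(fits) <- colnames(values)
  structure(fits, class = "abnormality_model")
}

# total data log-likelihood of the event-based model:
# sum_s log sum_k pi_k L_s(k)
ebm_total_loglik <- function(LA, LN, ordering, prior) {
  lp <- sweep(stage_ll_from_components(LA, LN, ordering), 2, log(prior), "+")
  mx <- do.call(pmax, as.data.frame(lp))
  sum(mx + log(rowSums(exp(lp - mx))))
}

#' Fit the complete event-based model by stage-coupled EM
#'
#' Integrated estimation of the per-biomarker normal/abnormal mixtures, the
#' event sequence and the stage prior, maximising the total model likelihood
#' `sum_s log sum_k pi_k L_s(k)`. Per-biomarker mixtures fitted in isolation
#' are weakly identified when the two components overlap, so this routine
#' couples them through the shared stage structure: subjects are first
#' ranked by total biomarker burden and each mixture initialized from the
#' best burden changepoint; a generalized EM then alternates (i) stage
#' posteriors given the current model, (ii) re-estimation of each mixture
#' with subject weights `P(stage >= position)` and of the stage prior, and
#' (iii) a local search over the sequence (adjacent swaps and single-element
#' insertions) on the total likelihood. Several starts are run and the best
#' total likelihood kept. The reported sequence is then the probabilistic
#' Kendall-tau central ordering computed from the final posteriors over
#' patients, with event-centers, and subjects are staged under the final
#' model.
#'
#' @param values Processed biomarker matrix (subjects x K; harmonized,
#'   control-anchored, covariate-adjusted).
#' @param group Group labels.
#' @param control_label Control-group label (default `"HC"`).
#' @param n_starts Number of sequence starts (burden ordering, group-contrast
#'   ordering, then random; default 3).
#' @param max_outer Maximum generalized-EM sweeps per start (default 15).
#' @param exhaustive_limit Passed to [central_ordering()].
#' @return Object of class `ebm_fit`: `model` (`abnormality_model`),
#'   `posteriors`, `sequence` (`event_sequence`), `staging`
#'   (`stage_assignment`), `prior`, `total_loglik`.
#' @export
fit_ebm <- function(values, group, control_label = "HC", n_starts = 3,
                    max_outer = 15, exhaustive_limit = 7) {
  values <- as.matrix(values)
  n <- nrow(values); K <- ncol(values)
  patients <- group != control_label
  if (!any(patients) || all(patients)) stop("need both groups")

  run_start <- function(ordering, fits) {
    prior <- rep(1 / (K + 1), K + 1)
    ll_best <- -Inf
    for (it in seq_len(max_outer)) {
      cl <- component_loglik(values, fits)
      lp <- sweep(stage_ll_from_components(cl$LA, cl$LN, ordering), 2,
                  log(prior), "+")
      mx <- do.call(pmax, as.data.frame(lp))
      W <- exp(lp - mx)
      Q <- W / rowSums(W)
      prior <- pmax(colMeans(Q), 1e-8); prior <- prior / sum(prior)
      pos <- match(seq_len(K), ordering)
      for (j in seq_len(K)) {
        e <- rowSums(Q[, (pos[j] + 1):(K + 1), drop = FALSE])
        x <- values[, j]; se <- sum(e); sn <- n - se
        if (se < 2 || sn < 2) next
        mu_a <- sum(e * x) / se
        sd_a <- max(sqrt(sum(e * (x - mu_a)^2) / se), 5e-2)
        mu_n <- sum((1 - e) * x) / sn
        sd_n <- max(sqrt(sum((1 - e) * (x - mu_n)^2) / sn), 5e-2)
        if (mu_a > mu_n)
          fits[[j]][c("mu_n", "sd_n", "mu_a", "sd_a", "w_a")] <-
            list(mu_n, sd_n, mu_a, sd_a,
                 min(max(se / n, 1e-4), 1 - 1e-4))
      }
      cl <- component_loglik(values, fits)
      cur <- ebm_total_loglik(cl$LA, cl$LN, ordering, prior)
      # sequence step: adjacent-swap sweeps, then insertion passes
      repeat {
        improved <- FALSE
        for (m in seq_len(K - 1)) {
          cand <- ordering
          cand[c(m, m + 1)] <- cand[c(m + 1, m)]
          cll <- ebm_total_loglik(cl$LA, cl$LN, cand, prior)
          if (cll > cur + 1e-9) { ordering <- cand; cur <- cll
                                  improved <- TRUE }
        }
        if (!improved) break
      }
      repeat {
        improved <- FALSE
        for (i in seq_len(K)) for (jj in seq_len(K)) {
          if (i == jj) next
          cand <- append(ordering[-i], ordering[i], after = jj - 1)
          cll <- ebm_total_loglik(cl$LA, cl$LN, cand, prior)
          if (cll > cur + 1e-9) { ordering <- cand; cur <- cll
                                  improved <- TRUE }
        }
        if (!improved) break
      }
      if (cur - ll_best < 1e-6) { ll_best <- max(cur, ll_best); break }
      ll_best <- cur
    }
    list(ordering = ordering, fits = fits, prior = prior, ll = ll_best)
  }

  init <- changepoint_init(values)
  starts <- list(order(vapply(init, `[[`, numeric(1), "w_a"),
                       decreasing = TRUE),
                 order(colMeans(values[patients, , drop = FALSE]) -
                         colMeans(values[!patients, , drop = FALSE]),
                       decreasing = TRUE))
  if (n_starts > 2)
    starts <- c(starts, lapply(seq_len(n_starts - 2),
                               function(i) sample.int(K)))
  best <- NULL
  for (o0 in starts[seq_len(min(n_starts, length(starts)))]) {
    r <- run_start(as.integer(o0), init)
    if (is.null(best) || r$ll > best$ll) best <- r
  }

  P <- posterior_abnormality(best$fits, values)
  dimnames(P) <- dimnames(values)
  sequence <- central_ordering(P, patients,
                               exhaustive_limit = exhaustive_limit)
  staging <- em_refine(values, sequence, best$fits, max_iter = 1000)
  structure(list(model = best$fits, posteriors = P, sequence = sequence,
                 staging = staging, prior = best$prior,
                 total_loglik = best$ll),
            class = "ebm_fit")
}
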