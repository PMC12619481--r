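#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares observed correlations to anti-image partial correlations:
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal pairs,
#' where `q_ij` are the partial correlations obtained from the inverse of the
#' correlation matrix. Values near 1 indicate the items share enough common
#' variance for component extraction; below ~0.5 is conventionally
#' inadequate. A per-item analogue uses row sums.
#'
#' @param R Item correlation matrix (symmetric, unit diagonal, positive
#'   definite).
#' @return List with `kmo_overall` and `kmo_per_item`.
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("R must be symmetric")
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, p), tolerance = 1e-8)))
    stop("R must have unit diagonal (a correlation matrix)")
  Rinv <- tryCatch(solve(R), error = function(e) stop("R is singular"))
  Q <- -stats::cov2cor(Rinv)  # anti-image partial correlations off-diagonal
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  if (sum(r2) == 0)
    stop("no off-diagonal correlation structure; KMO undefined for identity R")
  list(kmo_overall = sum(r2) / (sum(r2) + sum(q2)),
       kmo_per_item = rowSums(r2) / (rowSums(r2) + rowSums(q2)))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity (no shared variance,
#' PCA pointless): `chi2 = -(n - 1 - (2p + 5)/6) * log det(R)` on
#' `p(p-1)/2` degrees of freedom. Significance licenses dimension reduction.
#'
#' @param R Correlation matrix.
#' @param n Sample size used to estimate `R` (must exceed `p`).
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (n <= p) stop("need n > p")
  d <- det(R)
  if (d <= 0) stop("R must be positive definite (det > 0)")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = as.integer(df),
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Principal component analysis of an item battery
#'
#' Eigendecomposition of the item correlation matrix (items are z-scored
#' internally, so the eigenvalues sum to the number of items and the
#' eigenvalue-threshold selection rules apply). Loadings are unit-norm
#' eigenvectors, sign-fixed so each vector's largest-magnitude entry is
#' positive; component scores are the z-scored items projected onto the
#' loadings. Sampling-adequacy diagnostics (KMO, Bartlett) are attached.
#'
#' @param x Numeric matrix/data.frame, subjects x items; more subjects than
#'   items, no missing values, no constant columns.
#' @param select_rule Rule used to set `n_selected`, see
#'   [select_components()].
#' @return Object of class `pca_model`: `eigenvalues`, `loadings`,
#'   `explained_fraction` (sums to 1), `scores`, `n_selected`, `adequacy`.
#' @export
fit_pca <- function(x, select_rule = "kaiser") {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("need at least 2 items")
  if (nrow(x) <= p) stop("need more subjects than items")
  if (anyNA(x)) stop("missing values not allowed")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant item column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  flip <- apply(e$vectors, 2, function(v) v[which.max(abs(v))] < 0)
  e$vectors[, flip] <- -e$vectors[, flip, drop = FALSE]
  rownames(e$vectors) <- colnames(x)
  colnames(e$vectors) <- paste0("PC", seq_len(p))
  model <- structure(list(
    eigenvalues = pmax(e$values, 0),
    loadings = e$vectors,
    explained_fraction = pmax(e$values, 0) / p,
    scores = z %*% e$vectors,
    adequacy = c(kmo(R), bartlett_sphericity(R, nrow(x))),
    n_selected = NA_integer_
  ), class = "pca_model")
  model$n_selected <- select_components(model, select_rule)
  model
}

#' Select the number of principal components to retain
#'
#' `kaiser`: count of eigenvalues greater than 1 (the operative rule for the
#' battery reductions). `jolliffe`: the smallest m whose cumulative explained
#' variance exceeds 70% with all m eigenvalues above 0.7. A warning is issued
#' when the two rules disagree.
#'
#' @param model A `pca_model`.
#' @param rule `"kaiser"` (default) or `"jolliffe"`.
#' @param quiet Suppress the disagreement warning.
#' @return Integer count of selected components.
#' @export
select_components <- function(model, rule = c("kaiser", "jolliffe"),
                              quiet = FALSE) {
  rule <- match.arg(rule)
  ev <- model$eigenvalues
  kaiser <- sum(ev > 1)
  cum <- cumsum(model$explained_fraction)
  ok <- which(cum > 0.7 & vapply(seq_along(ev), function(m) all(ev[1:m] > 0.7),
                                 logical(1)))
  jolliffe <- if (length(ok)) min(ok) else NA_integer_
  if (!quiet && !is.na(jolliffe) && kaiser != jolliffe)
    warning("component-selection rules disagree: kaiser = ", kaiser,
            ", jolliffe = ", jolliffe)
  as.integer(if (rule == "kaiser") kaiser else jolliffe)
}

#' Composite battery score from selected components
#'
#' Collapses the selected component scores into one per-subject scalar.
#' The default weights each component by its eigenvalue (explained
#' variance); `"equal"` takes the simple mean.
#'
#' @param model A `pca_model` with `n_selected >= 1`.
#' @param weights `"eigenvalue"` (default) or `"equal"`.
#' @return Numeric vector, one composite score per subject.
#' @export
composite_score <- function(model, weights = c("eigenvalue", "equal")) {
  weights <- match.arg(weights)
  m <- model$n_selected
  if (is.na(m) || m < 1) stop("no components selected")
  s <- model$scores[, seq_len(m), drop = FALSE]
  w <- if (weights == "eigenvalue") model$eigenvalues[seq_len(m)] else rep(1, m)
  drop(s %*% w) / sum(w)
}

#' Reduce one battery to component scores and a composite
#'
#' Convenience wrapper: z-scores the items against a reference subset, fits
#' the correlation-matrix PCA, selects components by the Kaiser rule and
#' returns the per-subject selected-component scores plus the composite.
#'
#' @param items Item-score matrix/data.frame.
#' @param reference Logical mask of reference rows for the z-scoring.
#' @param prefix Column-name prefix for the output scores.
#' @param weights Composite weighting, see [composite_score()].
#' @return List: `model` (`pca_model`), `scores` (subjects x selected,
#'   named `<prefix>_PC1..`), `composite` (named `<prefix>_PC`).
#' @export
reduce_battery <- function(items, reference, prefix = "PC",
                           weights = "eigenvalue") {
  z <- zscore_to_reference(items, reference)
  model <- fit_pca(z)
  if (model$n_selected < 1)
    stop("Kaiser rule selected no components for battery ", prefix)
  s <- model$scores[, seq_len(model$n_selected), drop = FALSE]
  colnames(s) <- paste0(prefix, "_PC", seq_len(ncol(s)))
  list(model = model, scores = s,
       composite = stats::setNames(list(composite_score(model, weights)),
                                   paste0(prefix, "_PC"))[[1]])
}
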