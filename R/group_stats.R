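#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Linear model `outcome ~ group + age + sex + education`; the group effect
#' is tested by the partial F comparing against the covariate-only model
#' (equivalent to the type-III test for a two-level factor). Adjusted group
#' means are predictions at the overall covariate means.
#'
#' @param outcome Numeric response.
#' @param group Two-or-more-level factor/character.
#' @param covariates data.frame with `age`, `sex`, `education` (any numeric
#'   columns are accepted and all are adjusted for).
#' @param variable Optional name recorded in the result.
#' @return data.frame row: `variable`, one `adj_mean_<level>` per group,
#'   `F`, `df1`, `df2`, `p`.
#' @export
ancova_compare <- function(outcome, group, covariates,
                           variable = "outcome") {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  dat <- data.frame(.y = outcome, .g = group, covariates)
  full <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(full)))) stop("rank-deficient design")
  reduced <- stats::lm(.y ~ . - .g, data = dat)
  a <- stats::anova(reduced, full)
  Fst <- a$F[2]; p <- a$`Pr(>F)`[2]
  if (is.na(Fst) && isTRUE(abs(a$`Sum of Sq`[2]) < 1e-8)) {
    # group term explains nothing beyond rounding: a true null
    Fst <- 0; p <- 1
  }
  nd <- dat[rep(1, nlevels(group)), , drop = FALSE]
  nd$.g <- factor(levels(group), levels = levels(group))
  for (v in names(covariates)) nd[[v]] <- mean(covariates[[v]])
  adj <- stats::predict(full, newdata = nd)
  out <- data.frame(variable = variable, F = Fst, df1 = a$Df[2],
                    df2 = a$Res.Df[2], p = p)
  for (i in seq_len(nlevels(group)))
    out[[paste0("adj_mean_", levels(group)[i])]] <- adj[i]
  out
}

#' Pooled-variance two-sample t-test
#'
#' Classic two-sided t-test with the pooled variance estimate and
#' `df = n_a + n_b - 2`; used for the EBM-stage comparison, where covariates
#' were already adjusted upstream of the model fit.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return List: `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, df = na + nb - 2L, p = 1))
    stop("zero pooled variance with unequal means")
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson statistic without continuity correction,
#' `sum (O - E)^2 / E` with expected counts from the margins, df = 1.
#'
#' @param table 2x2 matrix of counts.
#' @return List: `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row/column margin")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(E <= 0)) stop("all expected counts must be > 0")
  chi2 <- sum((table - E)^2 / E)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Partial correlation adjusting for covariates
#'
#' Pearson correlation between the OLS residuals of `x` and `y` on
#' (intercept + covariates); the p-value uses the t transform with
#' `df = n - k - 2` where k is the number of covariates. With no covariates
#' this reduces to the ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data.frame/matrix of covariates.
#' @return List: `r`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= k + 2) stop("need n > number of covariates + 2")
  if (k > 0) {
    Z <- cbind(1, as.matrix(as.data.frame(covariates)))
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  if (stats::sd(rx) <= 1e-12 * max(1, stats::sd(x)) ||
      stats::sd(ry) <= 1e-12 * max(1, stats::sd(y)))
    stop("constant residuals; correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' original order.
#'
#' @param p Vector of p-values in `[0,1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted comparisons for a table of outcomes, with FDR
#'
#' Runs [ancova_compare()] for every column of `outcomes` as one FDR family
#' and appends BH-adjusted p-values.
#'
#' @param outcomes data.frame/matrix of outcome variables.
#' @param group Group labels.
#' @param covariates data.frame with `age`, `sex`, `education`.
#' @return data.frame with one row per outcome, including `p_fdr`.
#' @export
compare_outcomes <- function(outcomes, group, covariates) {
  outcomes <- as.data.frame(outcomes)
  res <- do.call(rbind, lapply(names(outcomes), function(v)
    ancova_compare(outcomes[[v]], group, covariates, variable = v)))
  res$p_fdr <- bh_fdr(res$p)
  res
}

#' Partial-correlation grid between scores and clinical variables, with FDR
#'
#' Every (score, clinical) pair is tested with [partial_correlation()]; the
#' whole grid forms one BH-FDR family.
#'
#' @param scores data.frame of cognitive scores (rows = subjects).
#' @param clinical data.frame of clinical variables.
#' @param covariates data.frame with `age`, `sex`, `education`.
#' @return data.frame: `score`, `clinical`, `r`, `df`, `p`, `p_fdr`.
#' @export
correlation_grid <- function(scores, clinical, covariates) {
  scores <- as.data.frame(scores); clinical <- as.data.frame(clinical)
  grid <- expand.grid(score = names(scores), clinical = names(clinical),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    pc <- partial_correlation(scores[[grid$score[i]]],
                              clinical[[grid$clinical[i]]], covariates)
    data.frame(score = grid$score[i], clinical = grid$clinical[i],
               r = pc$r, df = pc$df, p = pc$p)
  }))
  res$p_fdr <- bh_fdr(res$p)
  res
}
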