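#' Z-score columns against a reference subset
#'
#' Centres and scales every column by the mean and sample standard deviation
#' (n-1 denominator) computed on the reference rows only, so reference rows
#' have mean 0 and sd 1 afterwards. Used to anchor biomarker scales to the
#' healthy-control group.
#'
#' @param x Numeric matrix or data.frame.
#' @param reference Logical mask (or index vector) selecting reference rows.
#' @return Matrix of z-scores, same dimensions as `x`.
#' @export
zscore_to_reference <- function(x, reference) {
  x <- as.matrix(x)
  ref <- x[reference, , drop = FALSE]
  if (nrow(ref) < 2) stop("reference subset needs at least 2 rows")
  mu <- colMeans(ref)
  sd <- apply(ref, 2, stats::sd)
  bad <- which(sd == 0 | !is.finite(sd))
  if (length(bad))
    stop("zero reference sd in column(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

#' Harmonize biomarker directions so that higher = more abnormal
#'
#' Columns whose direction flag says higher values are *better* (e.g. MoCA,
#' MMSE, recall counts) are negated; columns already scored with higher =
#' worse (e.g. TMT completion times) are left unchanged. Idempotent given the
#' updated flags it returns.
#'
#' @param x Numeric matrix or data.frame of biomarker values.
#' @param higher_is_worse Logical vector, one flag per column (or a manifest
#'   data.frame with columns `name` and `higher_is_worse`).
#' @return List with `values` (harmonized matrix) and `higher_is_worse`
#'   (all `TRUE`).
#' @export
harmonize_direction <- function(x, higher_is_worse) {
  x <- as.matrix(x)
  if (is.data.frame(higher_is_worse)) {
    m <- higher_is_worse
    idx <- match(colnames(x), m$name)
    if (anyNA(idx))
      stop("manifest missing direction flag for: ",
           paste(colnames(x)[is.na(idx)], collapse = ", "))
    higher_is_worse <- m$higher_is_worse[idx]
  }
  if (length(higher_is_worse) != ncol(x) || anyNA(higher_is_worse))
    stop("need one non-missing direction flag per column")
  flip <- !higher_is_worse
  x[, flip] <- -x[, flip, drop = FALSE]
  list(values = x, higher_is_worse = rep(TRUE, ncol(x)))
}

#' Remove linear covariate effects, fitted on a reference subset
#'
#' Fits, per column, an ordinary-least-squares model
#' `value ~ age + sex + education` on the reference rows only, then subtracts
#' the fitted values from all rows. Reference residuals have exactly zero
#' mean; disease-related signal in non-reference rows is preserved.
#'
#' @param x Numeric matrix or data.frame of biomarker values.
#' @param covariates data.frame with numeric columns `age`, `sex`,
#'   `education` aligned 1:1 with the rows of `x`.
#' @param reference Logical mask or index vector of reference rows.
#' @return Matrix of residualized values.
#' @export
residualize_covariates <- function(x, covariates, reference) {
  x <- as.matrix(x)
  need <- c("age", "sex", "education")
  if (!all(need %in% names(covariates)))
    stop("covariates must contain age, sex, education")
  X <- cbind(1, as.matrix(covariates[, need]))
  Xr <- X[reference, , drop = FALSE]
  if (qr(Xr)$rank < ncol(Xr))
    stop("design matrix rank-deficient on the reference subset")
  beta <- solve(crossprod(Xr), crossprod(Xr, x[reference, , drop = FALSE]))
  x - X %*% beta
}

#' Aggregate atlas regions into composite ROI features
#'
#' Averages gray-matter volumes of atlas regions into named composite
#' features, per hemisphere (suffixes `_L` / `_R` on the region columns)
#' plus any midline features (e.g. cerebellar vermis), reproducing the
#' 17-bilateral-features-plus-vermis = 35-column ROI scheme.
#'
#' @param regional Numeric matrix/data.frame of per-region GMV, columns named
#'   `<Region>_L` / `<Region>_R` (or a bare name for midline regions).
#' @param scheme Named list: feature name -> character vector of member
#'   region base names. Features listed in `midline` are not split by
#'   hemisphere.
#' @param midline Character vector of features that have no hemisphere split.
#' @return Matrix with one column per feature-hemisphere (ordered
#'   `<feature>_L`, `<feature>_R`, then midline features).
#' @export
aggregate_rois <- function(regional, scheme, midline = character()) {
  regional <- as.matrix(regional)
  cols <- colnames(regional)
  grab <- function(members, suffix) {
    wanted <- if (nzchar(suffix)) paste0(members, suffix) else members
    miss <- setdiff(wanted, cols)
    if (length(miss))
      stop("regions missing from input: ", paste(miss, collapse = ", "))
    rowMeans(regional[, wanted, drop = FALSE])
  }
  out <- list()
  for (f in names(scheme)) {
    if (f %in% midline) {
      out[[f]] <- grab(scheme[[f]], "")
    } else {
      out[[paste0(f, "_L")]] <- grab(scheme[[f]], "_L")
      out[[paste0(f, "_R")]] <- grab(scheme[[f]], "_R")
    }
  }
  do.call(cbind, out)
}

#' Default composite ROI scheme
#'
#' The 17 bilateral composite features (frontal, temporal, parietal,
#' occipital lobes, insula, cingulate, sensorimotor cortex, Broca's area,
#' cerebellum, hippocampus, parahippocampus, amygdala, caudate, putamen,
#' pallidum, nucleus accumbens, thalamus) plus the cerebellar vermis,
#' expressed over AAL-style region labels. The grouping is a label
#' convention; any region-level table using these base names works.
#'
#' @return List with `scheme` (feature -> member regions) and `midline`.
#' @export
default_roi_scheme <- function() {
  list(scheme = list(
    Frontal = c("Frontal_Sup", "Frontal_Mid", "Frontal_Inf_Orb"),
    Temporal = c("Temporal_Sup", "Temporal_Mid", "Temporal_Inf"),
    Parietal = c("Parietal_Sup", "Parietal_Inf", "Precuneus"),
    Occipital = c("Occipital_Sup", "Occipital_Mid", "Occipital_Inf"),
    Insula = "Insula",
    Cingulate = c("Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post"),
    Sensorimotor = c("Precentral", "Postcentral"),
    Broca = c("Frontal_Inf_Oper", "Frontal_Inf_Tri"),
    Cerebellum = c("Cerebelum_Crus1", "Cerebelum_Crus2"),
    Hippocampus = "Hippocampus",
    Parahippocampus = "ParaHippocampal",
    Amygdala = "Amygdala",
    Caudate = "Caudate",
    Putamen = "Putamen",
    Pallidum = "Pallidum",
    Accumbens = "Accumbens",
    Thalamus = "Thalamus",
    Vermis = c("Vermis_1_2", "Vermis_3", "Vermis_4_5")
  ), midline = "Vermis")
}

#' Full biomarker preprocessing pipeline
#'
#' Fixed order: (1) harmonize directions so higher = more abnormal,
#' (2) z-score against the healthy-control rows, (3) residualize linear
#' age/sex/education effects fitted on the controls. Optionally divides GMV
#' columns by total intracranial volume first (`tiv` supplied and
#' `tiv_correct = TRUE`).
#'
#' @param x Biomarker matrix/data.frame.
#' @param covariates data.frame with `age`, `sex`, `education`.
#' @param group Character/factor vector; rows equal to `ref_group` form the
#'   reference population.
#' @param higher_is_worse Direction flags (vector or manifest data.frame).
#' @param ref_group Reference group label (default `"HC"`).
#' @param tiv Optional per-subject total intracranial volume.
#' @param tiv_correct Divide by `tiv` before z-scoring (default `TRUE` when
#'   `tiv` is given).
#' @return Matrix of processed biomarker values (higher = more abnormal,
#'   controls centred at 0 with unit sd, covariate effects removed).
#' @export
preprocess_biomarkers <- function(x, covariates, group, higher_is_worse,
                                  ref_group = "HC", tiv = NULL,
                                  tiv_correct = !is.null(tiv)) {
  x <- as.matrix(x)
  if (!is.null(tiv) && tiv_correct) {
    if (any(tiv <= 0)) stop("tiv must be positive")
    x <- sweep(x, 1, tiv, "/")
  }
  ref <- group == ref_group
  if (!any(ref)) stop("no rows in reference group '", ref_group, "'")
  h <- harmonize_direction(x, higher_is_worse)
  z <- zscore_to_reference(h$values, ref)
  residualize_covariates(z, covariates, ref)
}
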