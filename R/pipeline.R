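#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis. Seeds for the individual
#' stages are derived from the root seed with fixed offsets, so e.g. changing
#' the number of bootstrap resamples does not perturb the simulation draws.
#'
#' @param bootstrap_B Bootstrap resamples for the positional-variance matrix
#'   (default 100); set to 0 to skip the bootstrap.
#' @param seed Root integer seed.
#' @param composite_weights Composite weighting, see [composite_score()].
#' @param exhaustive_limit Largest K solved by exhaustive ordering search.
#' @param tiv_correct Divide GMV columns by total intracranial volume when a
#'   `tiv` column is available.
#' @param ref_group Control-group label.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bootstrap_B = 100, seed = 1L,
                            composite_weights = "eigenvalue",
                            exhaustive_limit = 7, tiv_correct = TRUE,
                            ref_group = "HC") {
  if (bootstrap_B < 0) stop("bootstrap_B must be >= 0")
  structure(list(bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed),
                 composite_weights = composite_weights,
                 exhaustive_limit = exhaustive_limit,
                 tiv_correct = tiv_correct, ref_group = ref_group),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes preprocess -> battery PCA reduction -> event-based model ->
#' staging -> group statistics on an `ebm_cohort` (simulated or read from
#' CSV), and optionally writes all artifacts plus a machine-readable run
#' manifest to `outdir`. Identical config + seed gives identical outputs.
#'
#' The biomarker panel entering the EBM is the cohort's `biomarkers` table
#' after direction harmonization, z-scoring against controls and covariate
#' residualization. Battery items are reduced to Kaiser-selected principal
#' components and composites, which feed the ANCOVA and partial-correlation
#' layers.
#'
#' @param cohort An `ebm_cohort` (see [generate_cohort()] / [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; `NULL` keeps results in memory.
#' @return List of class `ebm_result`: `processed` (biomarker matrix),
#'   `pca` (per-battery reductions), `sequence` (`event_sequence`),
#'   `positional_variance` (or `NULL` when `bootstrap_B == 0`), `staging`
#'   (`stage_assignment`), `stage_test` (pooled t on normalized stage),
#'   `comparisons` (ANCOVA table), `correlations` (partial-correlation grid),
#'   `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(cohort, "ebm_cohort"))
  group <- cohort$covariates$group
  covs <- cohort$covariates[, c("age", "sex", "education")]
  ref <- group == config$ref_group
  if (!any(ref)) stop("pipeline: no subjects in reference group")

  processed <- preprocess_biomarkers(
    cohort$biomarkers, covs, group, cohort$manifest,
    ref_group = config$ref_group,
    tiv = cohort$covariates[["tiv"]],
    tiv_correct = config$tiv_correct && !is.null(cohort$covariates[["tiv"]]))

  items <- cohort$items
  if (is.data.frame(items)) {
    batteries <- unique(sub("_item[0-9]+$", "", names(items)))
    items <- lapply(stats::setNames(batteries, batteries), function(b)
      items[, grep(paste0("^", b, "_item"), names(items)), drop = FALSE])
  }
  pca <- lapply(names(items), function(b)
    reduce_battery(items[[b]], ref, prefix = b,
                   weights = config$composite_weights))
  names(pca) <- names(items)

  set.seed(config$seed + 101L)
  fit <- suppressWarnings(
    fit_ebm(processed, group, control_label = config$ref_group,
            exhaustive_limit = config$exhaustive_limit))
  fits <- fit$model
  P <- fit$posteriors
  sequence <- fit$sequence
  staging <- fit$staging

  pv <- NULL
  if (config$bootstrap_B > 0) {
    set.seed(config$seed + 202L)
    pv <- bootstrap_sequence(processed, group, B = config$bootstrap_B,
                             control_label = config$ref_group,
                             exhaustive_limit = config$exhaustive_limit)
  }

  ns <- staging$assignment$normalized_stage
  stage_test <- two_sample_t(ns[!ref], ns[ref])

  scores <- do.call(cbind, lapply(pca, function(r)
    cbind(r$scores, r$composite)))
  colnames(scores) <- unlist(lapply(names(pca), function(b)
    c(colnames(pca[[b]]$scores), paste0(b, "_PC"))))
  comparisons <- compare_outcomes(as.data.frame(scores), group, covs)

  clin_vars <- intersect(c("PBG", "FBG", "GLU", "MAlb", "duration"),
                         names(cohort$covariates))
  correlations <- NULL
  sig <- comparisons$variable[comparisons$p_fdr < 0.05]
  if (length(sig) && length(clin_vars)) {
    pat <- !ref
    correlations <- correlation_grid(
      as.data.frame(scores)[pat, sig, drop = FALSE],
      cohort$covariates[pat, clin_vars, drop = FALSE],
      covs[pat, , drop = FALSE])
  }

  result <- structure(list(processed = processed, pca = pca,
                           abnormality = fits, posteriors = P,
                           sequence = sequence, positional_variance = pv,
                           staging = staging, stage_test = stage_test,
                           comparisons = comparisons,
                           correlations = correlations, config = config),
                      class = "ebm_result")
  if (!is.null(outdir)) write_result(result, cohort, outdir)
  result
}

#' Write pipeline artifacts and a run manifest
#'
#' @param result An `ebm_result`.
#' @param cohort The cohort the result came from (for subject ids).
#' @param outdir Output directory.
#' @return Invisibly, the output directory.
#' @export
write_result <- function(result, cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seqd <- data.frame(position = seq_along(result$sequence$ordering),
                     biomarker = result$sequence$biomarkers[
                       result$sequence$ordering],
                     event_center = result$sequence$event_centers)
  utils::write.csv(seqd, file.path(outdir, "event_sequence.csv"),
                   row.names = FALSE)
  if (!is.null(result$positional_variance))
    utils::write.csv(result$positional_variance$F,
                     file.path(outdir, "positional_variance.csv"))
  st <- cbind(id = cohort$covariates$id, group = cohort$covariates$group,
              result$staging$assignment)
  utils::write.csv(st, file.path(outdir, "stages.csv"), row.names = FALSE)
  utils::write.csv(result$comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  if (!is.null(result$correlations))
    utils::write.csv(result$correlations,
                     file.path(outdir, "correlations.csv"), row.names = FALSE)
  manifest <- list(config = unclass(result$config),
                   r_version = as.character(getRversion()),
                   n_subjects = nrow(cohort$covariates),
                   K = ncol(result$processed),
                   stage_test = result$stage_test)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.event_sequence <- function(x, ...) {
  cat("Event sequence (earliest first):\n")
  lab <- if (is.null(x$biomarkers)) as.character(x$ordering)
         else x$biomarkers[x$ordering]
  print(data.frame(position = seq_along(x$ordering), biomarker = lab,
                   event_center = round(x$event_centers, 3)),
        row.names = FALSE)
  cat("total probabilistic Kendall distance:", format(x$total_distance), "\n")
  invisible(x)
}

#' @export
print.ebm_result <- function(x, ...) {
  cat("Event-based model pipeline result\n")
  cat("  biomarkers:", ncol(x$processed), " subjects:", nrow(x$processed), "\n")
  print(x$sequence)
  cat(sprintf("  stage t-test: t = %.3f, df = %d, p = %.4g\n",
              x$stage_test$t, x$stage_test$df, x$stage_test$p))
  invisible(x)
}
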