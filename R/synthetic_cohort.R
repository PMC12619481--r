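#' Battery presets for the neuropsychological item generator
#'
#' Item and factor counts for the three multi-item batteries that are reduced
#' by PCA before entering the event-based model: the California Verbal
#' Learning Test (episodic memory), the Stroop Color-Word Test (inhibitory
#' control) and the Wisconsin Card Sorting Test (cognitive flexibility).
#' Factor block sizes mirror the published component compositions
#' (immediate recall / delayed recall / intrusions / recognition for CVLT;
#' accuracy-and-speed / errors for STROOP; overall performance /
#' perseveration / abstraction / learning for WCST).
#'
#' @param loading Loading magnitude of each item on its assigned factor.
#' @param noise_sd Standard deviation of the item-specific Gaussian noise.
#' @return Named list of battery specifications, each with `n_items`,
#'   `n_factors`, `blocks` (items per factor), `loading` and `noise_sd`.
#' @export
battery_presets <- function(loading = 0.8, noise_sd = 0.6) {
  list(
    CVLT   = list(n_items = 18, n_factors = 4, blocks = c(7L, 5L, 4L, 2L),
                  loading = loading, noise_sd = noise_sd),
    STROOP = list(n_items = 11, n_factors = 2, blocks = c(9L, 2L),
                  loading = loading, noise_sd = noise_sd),
    WCST   = list(n_items = 18, n_factors = 4, blocks = c(9L, 3L, 4L, 2L),
                  loading = loading, noise_sd = noise_sd)
  )
}

#' Specify a synthetic two-group cohort with a ground-truth event sequence
#'
#' Defines the generative model for a patient/control cohort in which each of
#' K biomarkers transitions from a "normal" to an "abnormal" Gaussian
#' distribution at a fixed position in a ground-truth event sequence.
#' A subject at stage k has passed the first k events of the sequence.
#' Patients' and controls' stages are binomial with success probabilities
#' `p_stage_patient` > `p_stage_control`, giving overlapping but shifted
#' stage distributions (controls are generated from the same event process at
#' earlier stages, not as an all-normal group). Biomarker scales are
#' harmonized so that larger values are more abnormal.
#'
#' @param n_patients,n_controls Group sizes. Defaults are the study cohort
#'   sizes (119 patients, 87 controls).
#' @param K Number of biomarkers (events); must be >= 2.
#' @param mu_normal,sd_normal,mu_abnormal,sd_abnormal Per-biomarker component
#'   parameters, recycled to length `K`. `mu_abnormal` must exceed
#'   `mu_normal` for every biomarker. Default is a 2-sd separation
#'   (0 vs 2 with unit sds).
#' @param p_stage_patient,p_stage_control Binomial stage parameters; the
#'   patient value must exceed the control value. Defaults 0.55 / 0.45.
#' @param sequence Optional pinned ground-truth permutation of `1:K`
#'   (position 1 = earliest event). `NULL` draws a random permutation.
#' @param stages Optional pinned per-subject stages (patients first, then
#'   controls), integers in `0:K`; `NULL` draws binomial stages.
#' @param covariate_effects Named vector `c(age=, sex=, education=)` of
#'   linear, additive confound coefficients applied to every biomarker
#'   (age and education centred at 52 y and 12.8 y; sex coded 0/1).
#' @param batteries Battery item-generator specification, see
#'   [battery_presets()].
#' @param seed Integer seed used by [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 119, n_controls = 87, K = 10,
                        mu_normal = 0, sd_normal = 1,
                        mu_abnormal = 2, sd_abnormal = 1,
                        p_stage_patient = 0.55, p_stage_control = 0.45,
                        sequence = NULL, stages = NULL,
                        covariate_effects = c(age = 0.02, sex = 0.2,
                                              education = -0.05),
                        batteries = battery_presets(),
                        seed = 1L) {
  if (!is.numeric(K) || K < 2) stop("K must be >= 2")
  K <- as.integer(K)
  if (n_patients < 1 || n_controls < 1)
    stop("n_patients and n_controls must be positive")
  mu_normal <- rep_len(mu_normal, K); sd_normal <- rep_len(sd_normal, K)
  mu_abnormal <- rep_len(mu_abnormal, K); sd_abnormal <- rep_len(sd_abnormal, K)
  if (any(sd_normal <= 0)) stop("sd_normal must be > 0")
  if (any(sd_abnormal <= 0)) stop("sd_abnormal must be > 0")
  if (any(mu_abnormal <= mu_normal))
    stop("mu_abnormal must exceed mu_normal for every biomarker")
  if (p_stage_patient <= p_stage_control)
    stop("p_stage_patient must exceed p_stage_control")
  if (!is.null(sequence)) {
    if (length(sequence) != K || !setequal(sequence, seq_len(K)))
      stop("sequence must be a permutation of 1:K")
    sequence <- as.integer(sequence)
  }
  n <- n_patients + n_controls
  if (!is.null(stages)) {
    if (length(stages) != n || any(stages < 0 | stages > K))
      stop("stages must give one value in 0:K per subject")
    stages <- as.integer(stages)
  }
  for (b in names(batteries)) {
    bb <- batteries[[b]]
    if (bb$n_items < bb$n_factors || bb$n_factors < 1)
      stop("batteries: need n_items >= n_factors >= 1 in ", b)
    if (bb$noise_sd < 0) stop("batteries: noise_sd must be >= 0 in ", b)
    if (any(bb$blocks < 1))
      stop("batteries: every factor must load on at least one item in ", b)
    if (sum(bb$blocks) != bb$n_items)
      stop("batteries: blocks must partition the items in ", b)
  }
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    K = K, mu_normal = mu_normal, sd_normal = sd_normal,
    mu_abnormal = mu_abnormal, sd_abnormal = sd_abnormal,
    p_stage_patient = p_stage_patient, p_stage_control = p_stage_control,
    sequence = sequence, stages = stages,
    covariate_effects = covariate_effects,
    batteries = batteries, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Group-specific covariate/chemistry parameters (means, sds) matching the
# demographic table of the study cohort. Used only to exercise the
# covariate-adjustment and correlation layers.
.covariate_params <- list(
  patient = list(age = c(54.871, 9.074), education = c(12.020, 3.063),
                 p_male = 87 / 119,
                 FBG = c(7.942, 2.910), PBG = c(10.977, 4.186),
                 GLU = c(8.503, 2.848), HbA1c = c(8.575, 2.060),
                 MAlb = c(79.703, 151.511), duration = c(9.632, 7.037)),
  control = list(age = c(49.922, 7.621), education = c(13.663, 3.888),
                 p_male = 50 / 87,
                 FBG = c(3.972, 2.436), PBG = c(7.320, 0.910),
                 GLU = c(5.978, 1.025), HbA1c = c(5.561, 0.297),
                 MAlb = c(17.420, 11.797), duration = c(0, 0))
)

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a full cohort from a [cohort_spec()]: covariates and clinical
#' chemistry, stage-dependent biomarker values, and factor-structured battery
#' items. For a subject at stage k, biomarkers at sequence positions `<= k`
#' are drawn from their abnormal distribution and later positions from their
#' normal distribution; linear covariate confounds are then added.
#'
#' @param spec A `cohort_spec`.
#' @param seed Optional seed overriding `spec$seed`.
#' @return An object of class `ebm_cohort`: a list with `covariates`
#'   (data.frame: id, group, age, sex, education, clinical chemistry),
#'   `biomarkers` (data.frame of K columns `bm01..`), `items` (named list of
#'   per-battery item data.frames), `manifest` (biomarker direction flags,
#'   all `higher_is_worse = TRUE` on the generated scale) and
#'   `ground_truth` (list: `sequence`, `event_centers`, `stages`, `group`).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed else as.integer(seed))
  K <- spec$K
  n <- spec$n_patients + spec$n_controls
  group <- rep(c("T2DM", "HC"), c(spec$n_patients, spec$n_controls))

  sequence <- if (is.null(spec$sequence)) sample.int(K) else spec$sequence
  stages <- if (is.null(spec$stages)) {
    as.integer(ifelse(group == "T2DM",
                      stats::rbinom(n, K, spec$p_stage_patient),
                      stats::rbinom(n, K, spec$p_stage_control)))
  } else spec$stages

  covs <- do.call(rbind, lapply(c("T2DM", "HC"), function(g) {
    pp <- .covariate_params[[if (g == "T2DM") "patient" else "control"]]
    ng <- if (g == "T2DM") spec$n_patients else spec$n_controls
    data.frame(
      group = g,
      age = stats::rnorm(ng, pp$age[1], pp$age[2]),
      sex = stats::rbinom(ng, 1, pp$p_male),
      education = pmax(0, stats::rnorm(ng, pp$education[1], pp$education[2])),
      FBG = stats::rnorm(ng, pp$FBG[1], pp$FBG[2]),
      PBG = stats::rnorm(ng, pp$PBG[1], pp$PBG[2]),
      GLU = stats::rnorm(ng, pp$GLU[1], pp$GLU[2]),
      HbA1c = stats::rnorm(ng, pp$HbA1c[1], pp$HbA1c[2]),
      MAlb = stats::rnorm(ng, pp$MAlb[1], pp$MAlb[2]),
      duration = pmax(0, stats::rnorm(ng, pp$duration[1], pp$duration[2]))
    )
  }))
  covs <- cbind(id = sprintf("S%03d", seq_len(n)), covs)
  rownames(covs) <- NULL

  # event at sequence position m has occurred for subjects with stage >= m;
  # biomarker ids are sequence[m]
  bm <- matrix(NA_real_, n, K)
  for (m in seq_len(K)) {
    j <- sequence[m]
    occurred <- stages >= m
    bm[, j] <- ifelse(occurred,
                      stats::rnorm(n, spec$mu_abnormal[j], spec$sd_abnormal[j]),
                      stats::rnorm(n, spec$mu_normal[j], spec$sd_normal[j]))
  }
  ce <- spec$covariate_effects
  confound <- ce[["age"]] * (covs$age - 52) + ce[["sex"]] * covs$sex +
    ce[["education"]] * (covs$education - 12.8)
  bm <- bm + confound
  colnames(bm) <- sprintf("bm%02d", seq_len(K))
  biomarkers <- as.data.frame(bm)

  items <- lapply(spec$batteries, function(bb) {
    fs <- matrix(stats::rnorm(n * bb$n_factors), n, bb$n_factors)
    fs[, 1] <- fs[, 1] - 0.8 * (group == "T2DM")
    generate_battery_items(bb, fs)
  })
  for (b in names(items))
    colnames(items[[b]]) <- sprintf("%s_item%02d", b, seq_len(ncol(items[[b]])))

  structure(list(
    covariates = covs, biomarkers = biomarkers, items = items,
    manifest = data.frame(name = colnames(bm),
                          higher_is_worse = TRUE),
    ground_truth = list(sequence = sequence,
                        event_centers = (seq_len(K) - 0.5) / K,
                        stages = stages, group = group)
  ), class = "ebm_cohort")
}

#' Generate item scores from latent factor scores
#'
#' Each item loads on exactly one factor with magnitude `loading`
#' (block-diagonal loading structure) plus independent Gaussian noise:
#' `item = loading * factor + N(0, noise_sd^2)`. With zero noise, PCA on the
#' items recovers exactly `n_factors` non-zero eigenvalues.
#'
#' @param battery One element of [battery_presets()] (fields `n_items`,
#'   `n_factors`, `blocks`, `loading`, `noise_sd`).
#' @param factor_scores Numeric matrix, subjects x `n_factors`.
#' @return data.frame of item scores, subjects x `n_items`.
#' @export
generate_battery_items <- function(battery, factor_scores) {
  factor_scores <- as.matrix(factor_scores)
  if (ncol(factor_scores) != battery$n_factors)
    stop("factor_scores must have n_factors = ", battery$n_factors, " columns")
  if (any(battery$blocks < 1))
    stop("every factor must load on at least one item")
  L <- matrix(0, battery$n_items, battery$n_factors)
  row0 <- 0
  for (f in seq_len(battery$n_factors)) {
    L[row0 + seq_len(battery$blocks[f]), f] <- battery$loading
    row0 <- row0 + battery$blocks[f]
  }
  n <- nrow(factor_scores)
  x <- factor_scores %*% t(L)
  if (battery$noise_sd > 0)
    x <- x + matrix(stats::rnorm(n * battery$n_items, 0, battery$noise_sd),
                    n, battery$n_items)
  as.data.frame(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `covariates.csv`, `battery_items.csv` (all batteries side by side,
#' columns prefixed by battery name), `biomarkers.csv`,
#' `biomarker_manifest.csv` (direction flags), `ground_truth.csv` (biomarker,
#' true sequence position, event center) plus per-subject `stages` therein,
#' and `data_dictionary.txt`.
#'
#' @param cohort An `ebm_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ebm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- cohort$ground_truth
  K <- length(gt$sequence)
  paths <- c(
    covariates = file.path(dir, "covariates.csv"),
    items = file.path(dir, "battery_items.csv"),
    biomarkers = file.path(dir, "biomarkers.csv"),
    manifest = file.path(dir, "biomarker_manifest.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    stages = file.path(dir, "true_stages.csv"),
    dictionary = file.path(dir, "data_dictionary.txt")
  )
  utils::write.csv(cohort$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(cbind(id = cohort$covariates$id,
                         do.call(cbind, unname(cohort$items))),
                   paths["items"], row.names = FALSE)
  utils::write.csv(cbind(id = cohort$covariates$id, cohort$biomarkers),
                   paths["biomarkers"], row.names = FALSE)
  utils::write.csv(cohort$manifest, paths["manifest"], row.names = FALSE)
  pos <- match(seq_len(K), gt$sequence)
  utils::write.csv(data.frame(biomarker = colnames(cohort$biomarkers),
                              true_position = pos,
                              event_center = gt$event_centers[pos]),
                   paths["ground_truth"], row.names = FALSE)
  utils::write.csv(data.frame(id = cohort$covariates$id, group = gt$group,
                              true_stage = gt$stages),
                   paths["stages"], row.names = FALSE)
  writeLines(c(
    "covariates.csv: id, group (T2DM/HC), age (years), sex (1=male),",
    "  education (years), FBG/PBG/GLU (mmol/L), HbA1c (%), MAlb (mg/L),",
    "  duration (years of disease; 0 for HC)",
    "battery_items.csv: id + <BATTERY>_itemNN raw item scores",
    "biomarkers.csv: id + bmNN biomarker values (higher = more abnormal)",
    "biomarker_manifest.csv: name, higher_is_worse (direction flag)",
    "ground_truth.csv: biomarker, true_position (1 = earliest event),",
    "  event_center in [0,1]",
    "true_stages.csv: id, group, true_stage in 0..K"
  ), paths["dictionary"])
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the CSV files.
#' @return An `ebm_cohort` (with `items` as one combined data.frame and
#'   ground truth if present).
#' @export
read_cohort <- function(dir) {
  covs <- utils::read.csv(file.path(dir, "covariates.csv"))
  biom <- utils::read.csv(file.path(dir, "biomarkers.csv"))
  items <- utils::read.csv(file.path(dir, "battery_items.csv"))
  manifest <- utils::read.csv(file.path(dir, "biomarker_manifest.csv"))
  gt <- NULL
  gtp <- file.path(dir, "ground_truth.csv")
  stp <- file.path(dir, "true_stages.csv")
  if (file.exists(gtp) && file.exists(stp)) {
    g <- utils::read.csv(gtp); s <- utils::read.csv(stp)
    gt <- list(sequence = match(seq_len(nrow(g)), g$true_position),
               event_centers = sort(g$event_center),
               stages = s$true_stage, group = s$group)
  }
  structure(list(covariates = covs,
                 biomarkers = biom[, setdiff(names(biom), "id"), drop = FALSE],
                 items = items[, setdiff(names(items), "id"), drop = FALSE],
                 manifest = manifest, ground_truth = gt),
            class = "ebm_cohort")
}
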