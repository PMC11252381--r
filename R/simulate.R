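#' Planted progression trajectories
#'
#' Two canonical event sequences over the 17-region atlas: a
#' cortical-predominant trajectory that starts with volume loss in Broca's
#' area, spreads to the fronto-insular cortex and the rest of the
#' neocortex, and reaches the subcortex last; and a
#' subcortical-predominant trajectory that starts in the hippocampus,
#' spreads to the amygdala and parahippocampus, then accumbens and
#' caudate, before affecting the cortex. Events are laid out in waypoint
#' waves: every region crosses z = 1 in trajectory order, then z = 2, then
#' z = 3, so within each biomarker thresholds appear in increasing order
#' by construction.
#'
#' @param spec a [sustain_spec()] over the default 17-region atlas
#' @return a list of two `event_sequence` objects
#' @export
default_trajectories <- function(spec = sustain_spec()) {
  cortical_first <- c(
    "Broca's area", "insula", "frontal lobe", "temporal lobe", "cingulate",
    "parietal lobe", "sensorimotor", "occipital lobe", "cerebellum",
    "thalamus", "hippocampus", "parahippocampus", "amygdala", "caudate",
    "putamen", "pallidum", "accumbens")
  subcortical_first <- c(
    "hippocampus", "amygdala", "parahippocampus", "accumbens", "caudate",
    "putamen", "pallidum", "thalamus", "insula", "temporal lobe",
    "frontal lobe", "Broca's area", "cingulate", "parietal lobe",
    "sensorimotor", "occipital lobe", "cerebellum")
  build <- function(roi_order) {
    idx <- match(roi_order, spec$biomarkers)
    if (anyNA(idx)) stop("trajectory regions must match the spec biomarkers")
    bio <- rep(idx, times = length(spec$waypoints))
    z <- rep(spec$waypoints, each = length(idx))
    event_sequence(bio, z, spec)
  }
  list(cortical_first = build(cortical_first),
       subcortical_first = build(subcortical_first))
}

#' Simulation configuration
#'
#' Defines the synthetic multi-site cohort: planted trajectories, subtype
#' mixture, stage occupancy, measurement noise, site effects, covariate
#' effects and the clinical-score model. Defaults emulate the study
#' conditions: two trajectories with subtype fractions 0.62/0.38, uniform
#' stage occupancy, unit control SD, three sites with additive shifts of
#' +/- 0.3 control SD and scale factors 0.9-1.1, and clinical scores
#' weakly tied to stage (target stage-duration Spearman around 0.1).
#'
#' @param n_patients,n_controls cohort sizes
#' @param subtype_fractions mixture probabilities, summing to 1
#' @param planted_sequences list of `event_sequence` objects, one per
#'   subtype (default [default_trajectories()])
#' @param stage_distribution probabilities over stages `0..E`
#'   (default uniform)
#' @param noise_sd measurement noise SD in control-SD units (default 1)
#' @param site_shift,site_scale per-site additive shift (volume units) and
#'   multiplicative noise scale; their common length sets the site count
#' @param beta_age,beta_age2,beta_sex,beta_tiv covariate effects on volume
#' @param control_sd nominal control SD per ROI in volume units; planted
#'   deviations are `control_sd * g(stage)` (default 1)
#' @param duration_shape,duration_scale,duration_stage_coef illness
#'   duration model: `Gamma(shape, scale) + coef * stage` years
#' @param subscales named list of clinical subscale generators, each
#'   `list(base, sd, slopes)` with one slope (points per year of illness
#'   duration) per subtype
#' @param spec a [sustain_spec()]
#' @param seed integer seed
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_patients = 800,
                       n_controls = 800,
                       subtype_fractions = c(0.62, 0.38),
                       planted_sequences = NULL,
                       stage_distribution = NULL,
                       noise_sd = 1,
                       site_shift = c(-0.3, 0, 0.3),
                       site_scale = c(0.9, 1, 1.1),
                       beta_age = -0.02,
                       beta_age2 = -2e-4,
                       beta_sex = 0.3,
                       beta_tiv = 2e-3,
                       control_sd = 1,
                       duration_shape = 1.2,
                       duration_scale = 5,
                       duration_stage_coef = 0.06,
                       subscales = default_subscales(),
                       spec = sustain_spec(),
                       seed = 1) {
  if (is.null(planted_sequences)) planted_sequences <- default_trajectories(spec)
  if (abs(sum(subtype_fractions) - 1) > 1e-8 ||
      any(subtype_fractions < 0) || any(subtype_fractions > 1))
    stop("subtype_fractions must lie in [0,1] and sum to 1")
  if (length(planted_sequences) != length(subtype_fractions))
    stop("one planted sequence per subtype fraction required")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(site_shift) != length(site_scale))
    stop("site_shift and site_scale must have equal length")
  for (s in planted_sequences) validate_sequence(s, spec)
  if (is.null(stage_distribution))
    stage_distribution <- rep(1 / (spec$n_events + 1), spec$n_events + 1)
  if (length(stage_distribution) != spec$n_events + 1)
    stop("stage_distribution must cover stages 0..E")
  structure(as.list(environment()), class = "sim_config")
}

#' Default clinical subscale generators
#'
#' Baselines follow typical symptom-scale magnitudes; slopes (points per
#' year of illness duration, one per subtype) plant the qualitative
#' pattern of diverging symptom trajectories: negative and
#' depression/anxiety symptoms worsen with duration only in subtype 1,
#' positive symptoms decline with duration in both subtypes. The `sd`
#' values are residual spreads about the duration trend (not full cohort
#' SDs, which also carry the duration spread and subtype mixing); for the
#' trend-carrying subscales they are calibrated so the planted
#' subtype-specific worsening is detectable at the design's sample size.
#'
#' @return named list of `list(base, sd, slopes)` generators
#' @export
default_subscales <- function() {
  list(
    panss_positive = list(base = 19.5, sd = 6.5, slopes = c(-0.25, -0.25)),
    panss_negative = list(base = 16.8, sd = 3.0, slopes = c(0.15, 0)),
    panss_general = list(base = 37.0, sd = 11.0, slopes = c(-0.3, -0.3)),
    panss_depression_anxiety = list(base = 11.2, sd = 3.2,
                                    slopes = c(0.10, 0))
  )
}

#' ROI column names used in cohort tables
#' @param atlas a [roi_atlas()]
#' @return sanitized column names, prefixed with `roi_`
#' @export
roi_columns <- function(atlas = roi_atlas()) {
  paste0("roi_", gsub("[^a-z0-9]+", "_", tolower(atlas$names)))
}

#' Generate a synthetic multi-site cohort
#'
#' Controls are drawn around site- and covariate-dependent means with
#' Gaussian noise. Each patient receives a (subtype, stage) pair from the
#' configured distributions; the patient's expected ROI volume is the
#' control-model mean minus `control_sd * g(stage, roi)` where `g` is the
#' expected z-score surface of the planted trajectory. Simulation truth is
#' stored in `true_subtype` / `true_stage` columns which no inference
#' stage reads.
#'
#' @param config a [sim_config()]
#' @param atlas a [roi_atlas()]; defaults to an atlas over the
#'   configuration's biomarkers
#' @return a `cohort_table` data frame
#' @export
generate_cohort <- function(config, atlas = NULL) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$spec
  atlas <- atlas %||% roi_atlas(spec$biomarkers)
  set.seed(config$seed)
  n_sites <- length(config$site_shift)
  n <- config$n_patients + config$n_controls
  group <- rep(c("patient", "control"),
               c(config$n_patients, config$n_controls))
  site <- c(sample(rep_len(seq_len(n_sites), config$n_patients)),
            sample(rep_len(seq_len(n_sites), config$n_controls)))
  if (min(table(factor(site[group == "patient"], levels = seq_len(n_sites)))) < 2 ||
      min(table(factor(site[group == "control"], levels = seq_len(n_sites)))) < 2)
    stop("need at least 2 patients and 2 controls per site for residualization")
  age <- pmin(pmax(rnorm(n, 33, 12), 18), 65)
  sex <- rbinom(n, 1, 0.45)
  tiv <- rnorm(n, 1500, 150)

  K <- length(config$subtype_fractions)
  true_subtype <- rep(NA_integer_, n)
  true_stage <- rep(NA_integer_, n)
  pat <- which(group == "patient")
  true_subtype[pat] <- sample.int(K, length(pat), replace = TRUE,
                                  prob = config$subtype_fractions)
  true_stage[pat] <- sample.int(spec$n_events + 1, length(pat),
                                replace = TRUE,
                                prob = config$stage_distribution) - 1L

  B <- length(atlas$names)
  G <- vapply(config$planted_sequences,
              function(s) expected_matrix(s, spec),
              matrix(0, spec$n_events + 1, B))
  mu <- 10 +
    config$beta_age * age + config$beta_age2 * age^2 +
    config$beta_sex * sex + config$beta_tiv * tiv
  vol <- matrix(mu, n, B) +
    matrix(config$site_shift[site], n, B) +
    config$site_scale[site] * matrix(rnorm(n * B, 0, config$noise_sd), n, B)
  for (i in pat) {
    g <- G[true_stage[i] + 1, , true_subtype[i]]
    vol[i, ] <- vol[i, ] - config$control_sd * atlas$loss_direction * g
  }
  colnames(vol) <- roi_columns(atlas)
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    group = group, site = factor(site),
                    age = age, sex = sex, tiv = tiv,
                    vol,
                    true_subtype = true_subtype,
                    true_stage = true_stage,
                    check.names = FALSE)
  structure(out, class = c("cohort_table", "data.frame"),
            atlas = atlas, spec = spec)
}

#' Add clinical scores to a simulated cohort
#'
#' Illness duration is drawn as `Gamma(shape, scale) + coef * true_stage`
#' years, giving the configured weak positive association between stage
#' and duration. Each subscale is linear in duration with a
#' subtype-specific slope plus Gaussian noise. Controls receive `NA`.
#'
#' @param cohort a `cohort_table` carrying `true_stage`
#' @param config the [sim_config()] used to generate it
#' @param noise_sd optional override of the subscale noise SDs (e.g. 0 for
#'   exact linear scores)
#' @return the cohort with `illness_duration` and subscale columns added
#' @export
generate_clinical <- function(cohort, config, noise_sd = NULL) {
  if (is.null(cohort$true_stage))
    stop("cohort lacks true_stage; clinical generation needs simulation truth")
  pat <- which(cohort$group == "patient")
  stage <- cohort$true_stage[pat]
  subtype <- cohort$true_subtype[pat]
  duration <- rgamma(length(pat), shape = config$duration_shape,
                     scale = config$duration_scale) +
    config$duration_stage_coef * stage
  cohort$illness_duration <- NA_real_
  cohort$illness_duration[pat] <- duration
  for (nm in names(config$subscales)) {
    sub <- config$subscales[[nm]]
    sdv <- if (is.null(noise_sd)) sub$sd else noise_sd
    val <- sub$base + sub$slopes[subtype] * duration +
      rnorm(length(pat), 0, sdv)
    cohort[[nm]] <- NA_real_
    cohort[[nm]][pat] <- val
  }
  cohort
}

#' Drop simulation-truth columns
#'
#' The inference stages operate on measured data only; this whitelist
#' enforcement removes every `true_*` column.
#'
#' @param cohort a `cohort_table`
#' @return the cohort without simulation-truth columns
#' @export
strip_truth <- function(cohort) {
  cohort[, !grepl("^true_", names(cohort)), drop = FALSE]
}

#' Write / read a cohort table
#'
#' Tab-separated values with a header row plus a sidecar JSON column
#' dictionary (`<path>.json`).
#'
#' @param cohort a `cohort_table`
#' @param path file path for the TSV
#' @return `path`, invisibly (write); a `cohort_table` (read)
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  atlas <- attr(cohort, "atlas")
  dict <- list(
    columns = as.list(setNames(
      ifelse(grepl("^roi_", names(cohort)), "ROI gray-matter volume",
             "covariate/identifier/clinical"), names(cohort))),
    roi_names = if (!is.null(atlas)) atlas$names else NULL)
  jsonlite::write_json(dict, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.delim(path, check.names = FALSE)
  out$site <- factor(out$site)
  structure(out, class = c("cohort_table", "data.frame"))
}
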