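#' Pipeline run configuration
#'
#' One master seed drives every random stage through deterministic child
#' seeds, so a run is reproducible and resumable stage by stage.
#'
#' @param out_dir output directory for stage artifacts
#' @param sim a [sim_config()] for the simulate stage
#' @param spec a [sustain_spec()]
#' @param settings a [sustain_settings()]
#' @param K_range candidate subtype counts for model selection
#' @param n_repeats Dice cross-validation repeats
#' @param K number of subtypes for the final fit (`NULL`: use the chosen K)
#' @param seed master seed
#' @param stages character vector of stages to run, in order
#' @return a `run_config` list
#' @export
run_config <- function(out_dir = "sustainr_run",
                       sim = sim_config(),
                       spec = sustain_spec(),
                       settings = sustain_settings(),
                       K_range = 2:3,
                       n_repeats = 3,
                       K = NULL,
                       seed = 1,
                       stages = c("simulate", "harmonize", "hopkins",
                                  "select_k", "fit", "assign",
                                  "characterize")) {
  structure(list(out_dir = out_dir, sim = sim, spec = spec,
                 settings = settings, K_range = K_range,
                 n_repeats = n_repeats, K = K, seed = seed,
                 stages = stages),
            class = "run_config")
}

# ---- lazy accessors: prefer in-memory state, else reload stage artifacts
# (this is what makes a run resumable from any completed stage)

get_cohort <- function(state, config) {
  if (is.null(state$cohort)) {
    path <- file.path(config$out_dir, "cohort.tsv")
    if (!file.exists(path)) stop("simulate stage has not run")
    state$cohort <- read_cohort(path)
  }
  state$cohort
}

get_harm <- function(state, config) {
  if (is.null(state$harm)) {
    path <- file.path(config$out_dir, "zscores.tsv")
    if (!file.exists(path)) stop("harmonize stage has not run")
    tab <- read.delim(path, check.names = FALSE)
    z <- as.matrix(tab[, -1])
    rownames(z) <- tab$subject_id
    cohort <- get_cohort(state, config)
    mask <- cohort$group[match(tab$subject_id, cohort$subject_id)] ==
      "control"
    state$harm <- list(z = z, control_mask = mask)
  }
  state$harm
}

# patient rows of the harmonized z table; never sees true_* columns
patient_z <- function(state, config) {
  h <- get_harm(state, config)
  as.matrix(h$z)[!h$control_mask, , drop = FALSE]
}

get_model <- function(state, config) {
  if (is.null(state$model)) {
    path <- file.path(config$out_dir, "model.json")
    if (!file.exists(path)) stop("fit stage has not run")
    state$model <- read_model_json(path)
  }
  state$model
}

get_assignment <- function(state, config) {
  if (is.null(state$assignment)) {
    Z <- patient_z(state, config)
    state$assignment <- sustain_assign(Z, get_model(state, config),
                                       config$spec)
  }
  state$assignment
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> harmonize -> hopkins -> select_k -> fit -> assign
#' -> characterize, writing each stage's artifacts (TSV tables, JSON
#' models and reports) under `config$out_dir` and returning a manifest
#' with per-stage file digests, timings and the seed trail. A stage
#' failure writes a manifest recording the completed stages before
#' re-raising; re-running with the remaining `stages` resumes from the
#' stored artifacts. Inference stages only ever see measured columns;
#' simulation truth is stripped before harmonization.
#'
#' @param config a [run_config()]
#' @return a `run_manifest` list (also written to `manifest.json`)
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("sustainr")),
                   seed = config$seed, stages = list())
  state <- new.env()
  runner <- list(
    simulate = function() {
      cohort <- generate_cohort(config$sim)
      cohort <- generate_clinical(cohort, config$sim)
      write_cohort(cohort, file.path(config$out_dir, "cohort.tsv"))
      state$cohort <- cohort
      "cohort.tsv"
    },
    harmonize = function() {
      cohort <- strip_truth(get_cohort(state, config))
      h <- harmonize(cohort, apply_outlier_filter = TRUE)
      state$harm <- h
      z <- as.matrix(h$z)
      write.table(data.frame(subject_id = rownames(z), z,
                             check.names = FALSE),
                  file.path(config$out_dir, "zscores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(h$outliers,
                           file.path(config$out_dir, "outliers.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      "zscores.tsv"
    },
    hopkins = function() {
      hr <- hopkins_statistic(patient_z(state, config),
                              seed = child_seed(config$seed, "hopkins"))
      state$hopkins <- hr
      jsonlite::write_json(unclass(hr),
                           file.path(config$out_dir, "hopkins.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      "hopkins.json"
    },
    select_k = function() {
      dc <- select_K(patient_z(state, config), K_range = config$K_range,
                     n_repeats = config$n_repeats, spec = config$spec,
                     settings = config$settings,
                     seed = child_seed(config$seed, "selectk"))
      state$dice <- dc
      jsonlite::write_json(list(K_range = dc$K_range, median = dc$median,
                                sd = dc$sd, values = dc$values,
                                chosen_K = dc$chosen_K),
                           file.path(config$out_dir, "dice_curve.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      "dice_curve.json"
    },
    fit = function() {
      K <- config$K %||% state$dice$chosen_K %||% 2
      model <- sustain_fit(patient_z(state, config), K, config$spec,
                           config$settings,
                           seed = child_seed(config$seed, "fit"))
      state$model <- model
      write_model_json(model, file.path(config$out_dir, "model.json"))
      "model.json"
    },
    assign = function() {
      a <- sustain_assign(patient_z(state, config),
                          get_model(state, config), config$spec)
      state$assignment <- a
      write.table(cbind(a$table, round(a$prob, 6)),
                  file.path(config$out_dir, "assignments.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      "assignments.tsv"
    },
    characterize = function() {
      ch <- get_cohort(state, config)
      a <- get_assignment(state, config)
      pat <- ch[ch$group == "patient", ]
      pat <- pat[pat$subject_id %in% a$table$subject, ]
      corr <- stage_correlates(
        a$table$stage,
        pat[, c("illness_duration", names(config$sim$subscales))])
      bins <- bin_duration(pat$illness_duration)
      traj <- symptom_trajectory(pat[, names(config$sim$subscales)],
                                 a$table$subtype, bins,
                                 pat[, c("age", "sex")], a$table$stage)
      morph <- intersubtype_morphometry(patient_z(state, config),
                                        a$table$subtype)
      write.table(corr, file.path(config$out_dir, "stage_correlates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(morph, file.path(config$out_dir, "morphometry.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(traj,
                           file.path(config$out_dir, "symptoms.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      "stage_correlates.tsv"
    })
  for (stage in config$stages) {
    t0 <- Sys.time()
    artifact <- tryCatch(runner[[stage]](), error = function(e) {
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    path <- file.path(config$out_dir, artifact)
    manifest$stages[[stage]] <- list(
      artifact = artifact,
      digest = unname(tools::md5sum(path)),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

#' Read a serialized model back
#'
#' @param path a JSON file written by [write_model_json()]
#' @return a `sustain_model` (without MCMC archive)
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- sustain_spec(biomarkers = obj$spec$biomarkers,
                       waypoints = obj$spec$waypoints,
                       z_max = obj$spec$z_max, sigma = obj$spec$sigma)
  seqs <- lapply(obj$sequences, function(s)
    event_sequence(s$biomarker, s$z, spec))
  settings <- do.call(sustain_settings,
                      obj$settings[names(formals(sustain_settings))])
  new_sustain_model(seqs, obj$fractions, obj$loglik, spec, settings,
                    obj$seed)
}

# order-stable hash of the configuration
config_hash <- function(config) {
  s <- jsonlite::serializeJSON(config)
  f <- tempfile()
  writeLines(s, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
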