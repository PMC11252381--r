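# shared fixtures built in code

# tiny model: 3 biomarkers, single waypoint z = 1, z_max anchor active
tiny_spec <- function(z_max = 2) {
  sustain_spec(biomarkers = c("a", "b", "c"), waypoints = 1, z_max = z_max)
}

# all 6 orderings of the tiny 3-event model
tiny_all_sequences <- function(spec = tiny_spec()) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) event_sequence(p, rep(1, 3), spec))
}

# z-score data generated noise-free-or-not from a sequence with uniform
# stages; returns list(Z, stage)
simulate_from_sequence <- function(seq, spec, n, noise_sd = 1, seed = 1) {
  set.seed(seed)
  M <- expected_matrix(seq, spec)
  stage <- sample.int(spec$n_events + 1, n, replace = TRUE) - 1L
  Z <- M[stage + 1, , drop = FALSE] +
    matrix(rnorm(n * length(spec$biomarkers), 0, noise_sd), n)
  list(Z = Z, stage = stage)
}

# independent naive oracle for the stage-marginal subject likelihood:
# literal sum over stages of products of normal densities
naive_subject_loglik <- function(z_row, seq, spec) {
  E <- spec$n_events
  total <- 0
  for (k in 0:E) {
    dens <- 1
    for (b in seq_along(spec$biomarkers)) {
      mu <- unname(expected_value(seq, k, b, spec))
      dens <- dens * dnorm(z_row[b], mu, spec$sigma[b])
    }
    total <- total + dens / (E + 1)
  }
  unname(log(total))
}

# Kendall tau between two event sequences (rank of each event's position)
sequence_tau <- function(seq_a, seq_b) {
  key_a <- paste(seq_a$biomarker, seq_a$z)
  key_b <- paste(seq_b$biomarker, seq_b$z)
  pos_b <- match(key_a, key_b)
  cor(seq_along(key_a), pos_b, method = "kendall")
}

# small planted two-subtype cohort harmonized to patient z-scores
planted_cohort_z <- function(n_patients = 800, n_controls = 800, seed = 11) {
  cfg <- sim_config(n_patients = n_patients, n_controls = n_controls,
                    seed = seed)
  cohort <- generate_cohort(cfg)
  h <- harmonize(strip_truth(cohort), apply_outlier_filter = FALSE)
  list(Z = as.matrix(h$z)[!h$control_mask, , drop = FALSE],
       truth = cohort[cohort$group == "patient",
                      c("true_subtype", "true_stage")],
       cohort = cohort, config = cfg)
}
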