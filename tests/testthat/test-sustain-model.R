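test_that("expected z-score surface interpolates waypoints and is monotone", {
  spec <- sustain_spec()
  set.seed(1)
  for (rep in 1:5) {
    sq <- random_sequence(spec)
    M <- expected_matrix(sq, spec)
    # stage 0 -> 0 for every biomarker
    expect_equal(unname(M[1, ]), rep(0, 17))
    # exact waypoint values at waypoint positions
    for (j in seq_len(nrow(sq)))
      expect_equal(M[j + 1, sq$biomarker[j]], sq$z[j])
    # monotone non-decreasing in stage, bounded by [0, z_max]
    expect_true(all(diff(M) > -1e-12))
    expect_true(all(M >= 0 & M <= max(spec$z_max) + 1e-12))
  }
})

test_that("a waypoint at the final stage drops the z_max anchor", {
  # toy: E = 4, biomarker b with waypoints {1,2} at positions 2 and 4
  spec <- sustain_spec(biomarkers = c("a", "b"), waypoints = c(1, 2),
                       z_max = 3)
  sq <- event_sequence(c(1, 2, 1, 2), c(1, 1, 2, 2), spec)
  expect_equal(expected_value(sq, 1, "b", spec), 0.5)
  expect_equal(expected_value(sq, 4, "b", spec), 2)  # not pulled to z_max
  # biomarker a ends at position 3 < E, so its z_max anchor is active
  expect_equal(expected_value(sq, 4, "a", spec), 3)
  expect_error(expected_value(sq, 5, "a", spec), "out of range")
})

test_that("subject log-likelihood matches the closed form and the naive oracle", {
  # one biomarker, one waypoint, datum 0: log(0.5*(phi(0) + phi(-1)))
  s1 <- sustain_spec(biomarkers = "b1", waypoints = 1, z_max = 1)
  sq1 <- event_sequence(1, 1, s1)
  expect_equal(subject_loglik(0, sq1, s1),
               log(0.5 * (dnorm(0) + dnorm(0, 1))), tolerance = 1e-12)
  expect_equal(subject_loglik(0, sq1, s1), -1.1380086, tolerance = 1e-6)
  # 3-biomarker toy against literal stage-by-stage summation
  spec <- tiny_spec()
  set.seed(2)
  for (sq in tiny_all_sequences(spec)) {
    z_row <- rnorm(3)
    expect_equal(subject_loglik(z_row, sq, spec),
                 naive_subject_loglik(z_row, sq, spec), tolerance = 1e-10)
  }
  expect_error(subject_loglik(c(0, NA, 1), tiny_all_sequences(spec)[[1]],
                              spec), "finite")
})

test_that("subject log-likelihood is invariant under biomarker relabeling", {
  spec <- tiny_spec()
  sq <- event_sequence(c(2, 3, 1), c(1, 1, 1), spec)
  z_row <- c(0.4, 1.2, -0.3)
  # permute biomarkers and the sequence identically
  perm <- c(3, 1, 2)
  sq_p <- event_sequence(perm[sq$biomarker], sq$z, spec)
  z_p <- z_row
  z_p[perm] <- z_row
  expect_equal(subject_loglik(z_row, sq, spec),
               subject_loglik(z_p, sq_p, spec), tolerance = 1e-12)
})

test_that("mixture log-likelihood reduces correctly and matches hand expansion", {
  spec <- tiny_spec()
  seqs <- tiny_all_sequences(spec)
  Z <- matrix(c(0.5, 1.4, -0.2, 2.1, 0.3, 0.9), 2, byrow = TRUE)
  m1 <- sustainr:::new_sustain_model(seqs[1], 1, NA, spec,
                                     sustain_settings(), 1)
  expect_equal(mixture_loglik(Z, m1, spec),
               sum(apply(Z, 1, subject_loglik, seqs[[1]], spec)),
               tolerance = 1e-12)
  # duplicated sequence with fractions (0.5, 0.5) collapses to K = 1
  m2 <- sustainr:::new_sustain_model(seqs[c(1, 1)], c(0.5, 0.5), NA, spec,
                                     sustain_settings(), 1)
  expect_equal(mixture_loglik(Z, m2, spec), mixture_loglik(Z, m1, spec),
               tolerance = 1e-12)
  # two-subject toy against the hand-expanded mixture
  m3 <- sustainr:::new_sustain_model(seqs[c(2, 5)], c(0.3, 0.7), NA, spec,
                                     sustain_settings(), 1)
  by_hand <- sum(log(
    0.3 * exp(apply(Z, 1, subject_loglik, seqs[[2]], spec)) +
    0.7 * exp(apply(Z, 1, subject_loglik, seqs[[5]], spec))))
  expect_equal(mixture_loglik(Z, m3, spec), by_hand, tolerance = 1e-10)
})

test_that("EM recovers a known sequence from noise-free data", {
  spec <- sustain_spec(biomarkers = paste0("m", 1:6), waypoints = 1,
                       z_max = 3)
  truth <- event_sequence(c(4, 1, 6, 2, 5, 3), rep(1, 6), spec)
  sim <- simulate_from_sequence(truth, spec, 120, noise_sd = 0, seed = 5)
  model <- optimize_sequences_em(sim$Z, 1, spec,
                                 sustain_settings(n_starts = 3), seed = 6)
  expect_equal(model$sequences[[1]]$biomarker, truth$biomarker)
  expect_equal(sum(model$fractions), 1)
  expect_error(optimize_sequences_em(sim$Z[1:2, ], 3, spec), "exceeds")
})

test_that("refitting with one more subtype never lowers the likelihood", {
  px <- planted_cohort_z(n_patients = 120, n_controls = 120, seed = 41)
  spec <- sustain_spec()
  set <- sustain_settings(n_starts = 2, split_restarts = 2)
  models <- fit_hierarchy(px$Z, 2, spec, set, seed = 3)
  expect_gte(models[[2]]$loglik, models[[1]]$loglik - 1e-6)
  expect_equal(length(models[[1]]$sequences), 1)
  expect_equal(models[[1]]$fractions, 1)
})

test_that("MCMC archives only valid sequences, is seed-reproducible, and finds the toy optimum", {
  spec <- tiny_spec()
  seqs <- tiny_all_sequences(spec)
  truth <- seqs[[4]]
  sim <- simulate_from_sequence(truth, spec, 200, noise_sd = 1, seed = 7)
  init <- sustainr:::new_sustain_model(seqs[1], 1, NA, spec,
                                       sustain_settings(), 1)
  ref <- mcmc_sequences(sim$Z, init, spec, n_iter = 500, seed = 9)
  # every archived sequence satisfies the ordering invariants
  for (it in c(1, 250, 500)) {
    arch_seq <- sustainr:::ids_to_seq(ref$archive$ids[[1]][it, ], spec)
    expect_silent(validate_sequence(arch_seq, spec))
  }
  # exhaustive enumeration over all 3! orderings is the oracle
  lls <- vapply(seqs, function(s)
    sum(apply(sim$Z, 1, subject_loglik, s, spec)), numeric(1))
  best <- seqs[[which.max(lls)]]
  expect_equal(ref$sequences[[1]]$biomarker, best$biomarker)
  # determinism under a fixed seed
  ref2 <- mcmc_sequences(sim$Z, init, spec, n_iter = 500, seed = 9)
  expect_identical(ref$archive$ids, ref2$archive$ids)
  expect_identical(ref$archive$loglik, ref2$archive$loglik)
  expect_error(mcmc_sequences(sim$Z, init, spec, n_iter = 0), "n_iter")
})

test_that("assignment is exact on noise-free profiles and normalizes posteriors", {
  spec <- tiny_spec()
  seqs <- tiny_all_sequences(spec)
  model <- sustainr:::new_sustain_model(seqs[c(1, 6)], c(0.5, 0.5), NA,
                                        spec, sustain_settings(), 1)
  M1 <- expected_matrix(seqs[[1]], spec)
  # subjects lying exactly on subtype 1's curve at stages 0..3
  Z <- M1
  a <- sustain_assign(Z, model, spec)
  expect_equal(a$table$stage, 0:3)
  expect_gte(min(a$prob[2:4, 1]), 0.5)
  # all-zero profile -> stage 0, and stage posteriors sum to 1
  expect_equal(a$table$stage[1], 0)
  expect_equal(rowSums(a$stage_posterior), rep(1, 4), tolerance = 1e-10)
  expect_equal(rowSums(a$prob), rep(1, 4), tolerance = 1e-10)
})

test_that("swapping the planted sequences only permutes the recovered model", {
  spec <- sustain_spec(biomarkers = paste0("m", 1:8), waypoints = 1,
                       z_max = 3)
  s1 <- event_sequence(1:8, rep(1, 8), spec)
  s2 <- event_sequence(8:1, rep(1, 8), spec)
  make_Z <- function(seq_list) {
    sim1 <- simulate_from_sequence(seq_list[[1]], spec, 150, seed = 11)
    sim2 <- simulate_from_sequence(seq_list[[2]], spec, 90, seed = 12)
    rbind(sim1$Z, sim2$Z)
  }
  set <- sustain_settings(n_starts = 2, split_restarts = 3)
  ma <- sustain_fit(make_Z(list(s1, s2)), 2, spec, set, seed = 13,
                    mcmc = FALSE)
  mb <- sustain_fit(make_Z(list(s2, s1)), 2, spec, set, seed = 13,
                    mcmc = FALSE)
  # each run recovers the same pair of trajectories, up to label order:
  # match each recovered sequence to its closest planted one
  best_tau <- function(model) {
    sapply(model$sequences, function(s)
      max(sequence_tau(s, s1), sequence_tau(s, s2)))
  }
  expect_true(all(best_tau(ma) >= 0.8))
  expect_true(all(best_tau(mb) >= 0.8))
  # and the two runs agree with each other after permutation matching
  cross <- outer(seq_along(ma$sequences), seq_along(mb$sequences),
                 Vectorize(function(i, j)
                   sequence_tau(ma$sequences[[i]], mb$sequences[[j]])))
  expect_gte(max(cross[1, ]), 0.8)
  expect_gte(max(cross[2, ]), 0.8)
})

test_that("models serialize to JSON and back", {
  spec <- tiny_spec()
  seqs <- tiny_all_sequences(spec)
  model <- sustainr:::new_sustain_model(seqs[c(2, 3)], c(0.4, 0.6), -12.3,
                                        spec, sustain_settings(), 99)
  path <- file.path(tempdir(), "model_test.json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$fractions, model$fractions)
  expect_equal(back$sequences[[1]]$biomarker, seqs[[2]]$biomarker)
  expect_equal(back$seed, 99)
  unlink(path)
})
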