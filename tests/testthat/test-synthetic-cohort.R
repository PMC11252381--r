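test_that("default trajectories start in Broca's area and hippocampus and enumerate all events", {
  spec <- sustain_spec()
  tr <- default_trajectories(spec)
  first1 <- tr$cortical_first[1, ]
  first2 <- tr$subcortical_first[1, ]
  expect_equal(spec$biomarkers[first1$biomarker], "Broca's area")
  expect_equal(first1$z, 1)
  expect_equal(spec$biomarkers[first2$biomarker], "hippocampus")
  expect_equal(first2$z, 1)
  for (s in tr) {
    expect_equal(nrow(s), 51)
    expect_equal(anyDuplicated(paste(s$biomarker, s$z)), 0L)
    expect_silent(validate_sequence(s, spec))
  }
})

test_that("generated cohorts are reproducible and planted counts follow the mixture", {
  cfg <- sim_config(n_patients = 1000, n_controls = 60, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # binomial oracle: n p +/- 3 sqrt(n p (1-p))
  n1 <- sum(a$true_subtype == 1, na.rm = TRUE)
  expect_gt(n1, 1000 * 0.62 - 3 * sqrt(1000 * 0.62 * 0.38))
  expect_lt(n1, 1000 * 0.62 + 3 * sqrt(1000 * 0.62 * 0.38))
  expect_false(any(is.na(a[, roi_columns()])))
  expect_true(all(is.na(a$true_subtype[a$group == "control"])))
})

test_that("noise-free patients sit exactly on the planted expected-z curve", {
  spec <- sustain_spec()
  cfg0 <- sim_config(n_patients = 40, n_controls = 40, noise_sd = 0,
                     site_shift = 0, site_scale = 1,
                     beta_age = 0, beta_age2 = 0, beta_sex = 0,
                     beta_tiv = 0, seed = 3)
  cohort <- generate_cohort(cfg0)
  pat <- cohort$group == "patient"
  V <- as.matrix(cohort[, roi_columns()])
  # stage-0 patients equal the control-model mean (10)
  s0 <- pat & cohort$true_stage == 0
  expect_true(any(s0))
  expect_equal(unname(V[s0, ]), matrix(10, sum(s0), 17), tolerance = 1e-12)
  # final-stage patients deviate by the maximum z (5 control SDs) on every
  # ROI except the one whose last waypoint sits at the final position,
  # which stays at its z = 3 waypoint (its z_max anchor is dropped)
  cfgE <- sim_config(n_patients = 10, n_controls = 10, noise_sd = 0,
                     site_shift = 0, site_scale = 1,
                     beta_age = 0, beta_age2 = 0, beta_sex = 0,
                     beta_tiv = 0,
                     stage_distribution = c(rep(0, spec$n_events), 1),
                     seed = 3)
  cohortE <- generate_cohort(cfgE)
  patE <- cohortE$group == "patient"
  VE <- as.matrix(cohortE[patE, roi_columns()])
  tr <- default_trajectories(spec)
  for (i in seq_len(nrow(VE))) {
    sq <- tr[[cohortE$true_subtype[patE][i]]]
    want <- rep(10 - 5, 17)
    want[sq$biomarker[spec$n_events]] <- 10 - 3
    expect_equal(unname(VE[i, ]), want, tolerance = 1e-12)
  }
})

test_that("planted z-deviations are recovered exactly through normative z-scoring", {
  spec <- sustain_spec()
  cfg <- sim_config(n_patients = 30, n_controls = 30, noise_sd = 0,
                    site_shift = 0, site_scale = 1, beta_age = 0,
                    beta_age2 = 0, beta_sex = 0, beta_tiv = 0, seed = 9)
  cohort <- generate_cohort(cfg)
  V <- as.matrix(cohort[, roi_columns()])
  z <- to_zscores(V, cohort$group == "control",
                  center = rep(10, 17), scale = rep(1, 17))
  tr <- default_trajectories(spec)
  pat <- which(cohort$group == "patient")
  for (i in pat) {
    g <- expected_matrix(tr[[cohort$true_subtype[i]]],
                         spec)[cohort$true_stage[i] + 1, ]
    expect_equal(unname(as.matrix(z)[i, ]), unname(g), tolerance = 1e-6)
  }
})

test_that("per-site control ROI distributions are Gaussian", {
  # KS non-rejection at alpha = 0.01 in >= 18 of 20 seeds
  pass <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_patients = 10, n_controls = 500, seed = 100 + s,
                      beta_age = 0, beta_age2 = 0, beta_sex = 0,
                      beta_tiv = 0)
    co <- generate_cohort(cfg)
    ctrl <- co[co$group == "control" & co$site == 1, ]
    x <- ctrl[[roi_columns()[1]]]
    p <- ks.test((x - mean(x)) / sd(x), "pnorm")$p.value
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 18L)
})

test_that("clinical scores track stage and planted subtype-specific slopes", {
  cfg <- sim_config(n_patients = 2000, n_controls = 20, seed = 21)
  cohort <- generate_clinical(generate_cohort(cfg), cfg)
  pat <- cohort$group == "patient"
  rho <- cor(cohort$true_stage[pat], cohort$illness_duration[pat],
             method = "spearman")
  expect_gt(rho, 0.05)
  expect_lt(rho, 0.3)
  # noise-free: subtype-1 negative symptoms rise from early to late bin
  c0 <- generate_clinical(generate_cohort(cfg), cfg, noise_sd = 0)
  p1 <- c0$group == "patient" & c0$true_subtype == 1
  bins <- bin_duration(c0$illness_duration)
  expect_gt(mean(c0$panss_negative[p1 & bins == "late"]),
            mean(c0$panss_negative[p1 & bins == "early"]))
  # zero slopes: bin means indistinguishable
  cfg0 <- cfg
  cfg0$subscales <- lapply(cfg0$subscales, function(s) {
    s$slopes <- c(0, 0); s
  })
  cz <- generate_clinical(generate_cohort(cfg0), cfg0, noise_sd = 0)
  pz <- cz$group == "patient"
  binz <- bin_duration(cz$illness_duration)
  expect_lt(diff(range(tapply(cz$panss_negative[pz], binz[pz], mean))),
            1e-9)
  # missing truth is an error
  expect_error(generate_clinical(strip_truth(cohort), cfg), "true_stage")
})

test_that("cohort round-trips through TSV with a sidecar dictionary", {
  cfg <- sim_config(n_patients = 12, n_controls = 12, seed = 2)
  cohort <- generate_clinical(generate_cohort(cfg), cfg)
  path <- file.path(tempdir(), "cohort_test.tsv")
  write_cohort(cohort, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(back$subject_id, cohort$subject_id)
  expect_equal(as.matrix(back[, roi_columns()]),
               as.matrix(cohort[, roi_columns()]), tolerance = 1e-8)
  unlink(c(path, paste0(path, ".json")))
})

test_that("too few subjects per site is rejected", {
  expect_error(generate_cohort(sim_config(n_patients = 3, n_controls = 40)),
               "per site")
})
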