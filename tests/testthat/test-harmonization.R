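make_design <- function(n, sites = 2, seed = 1) {
  set.seed(seed)
  data.frame(sex = rbinom(n, 1, 0.5),
             age = runif(n, 20, 60),
             site = factor(rep_len(seq_len(sites), n)),
             tiv = rnorm(n, 1500, 150))
}

test_that("residualize recovers planted covariate effects and centers null ROIs", {
  n <- 500
  design <- make_design(n, seed = 4)
  set.seed(5)
  # ROI 1: no covariate effect; ROI 2: planted age slope
  b_age <- 0.05
  V <- cbind(rnorm(n), 2 + b_age * design$age + rnorm(n))
  res <- residualize(V, design)
  expect_equal(dim(res), dim(V))
  # null-effect ROI: residuals equal centered volumes up to OLS noise
  expect_equal(res[, 1], V[, 1] - mean(V[, 1]), tolerance = 0.2)
  expect_lt(abs(mean(res[, 2])), 1e-10)
  # the fitted age coefficient is within 3 SE of the planted slope
  fit <- lm(V[, 2] ~ sex + age + I(age^2) + site + tiv, design)
  est <- summary(fit)$coefficients["age", ]
  expect_lt(abs(est["Estimate"] - b_age), 3 * est["Std. Error"])
})

test_that("rank-deficient designs are rejected with the offending column named", {
  design <- make_design(50)
  design$tiv <- 1500  # constant column
  expect_error(residualize(matrix(rnorm(50), 50, 1), design),
               "rank deficient.*tiv")
})

test_that("ComBat removes planted additive and multiplicative batch effects", {
  set.seed(8)
  n <- 400
  batch <- rep(c("s1", "s2"), each = n)
  # additive shift 0.5 SD on batch 2
  x_add <- rbind(matrix(rnorm(n * 3), n), matrix(rnorm(n * 3, 0.5), n))
  adj <- combat_adjust(x_add, batch)
  shift <- colMeans(adj[batch == "s2", ]) - colMeans(adj[batch == "s1", ])
  raw <- colMeans(x_add[batch == "s2", ]) - colMeans(x_add[batch == "s1", ])
  # the planted 0.5-SD shift is removed; what remains is the empirical-
  # Bayes-shrunken sampling noise of the batch means
  expect_lt(mean(abs(shift)), 0.05)
  expect_lt(max(abs(shift)), max(abs(raw)) / 5)
  # scale ratio 1.5 on batch 2
  x_sc <- rbind(matrix(rnorm(n * 3), n), matrix(rnorm(n * 3, 0, 1.5), n))
  adj2 <- combat_adjust(x_sc, batch)
  ratio <- apply(adj2[batch == "s2", ], 2, sd) /
    apply(adj2[batch == "s1", ], 2, sd)
  expect_true(all(ratio > 0.95 & ratio < 1.05))
})

test_that("ComBat edge contracts hold", {
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(combat_adjust(x, rep("one", 20)), x, tolerance = 1e-6,
               ignore_attr = TRUE)
  x2 <- rbind(x, x[1:2, ] * 0)  # a batch with zero variance
  expect_error(combat_adjust(x2, rep(c("a", "b"), c(20, 2))),
               "zero within-batch variance")
  expect_error(combat_adjust(x, rep(c("a", "b"), c(19, 1))),
               "at least 2 subjects")
})

test_that("z-scoring is sign-flipped and exact on controls", {
  x <- matrix(c(10, 11, 12, 9, 13, 10.5), ncol = 1)
  ctrl <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  z <- to_zscores(x, ctrl)
  # control column means 0, SDs 1
  expect_equal(mean(as.matrix(z)[ctrl, ]), 0, tolerance = 1e-12)
  expect_equal(sd(as.matrix(z)[ctrl, ]), 1, tolerance = 1e-12)
  # control exactly at the mean -> 0
  expect_equal(as.matrix(z)[2, 1], 0)
  # one control-SD below the mean -> +1; two above -> -2
  m <- mean(x[ctrl, 1]); s <- sd(x[ctrl, 1])
  z2 <- to_zscores(rbind(x, m - s, m + 2 * s),
                   c(ctrl, FALSE, FALSE))
  expect_equal(as.matrix(z2)[7, 1], 1)
  expect_equal(as.matrix(z2)[8, 1], -2)
  expect_error(to_zscores(matrix(c(1, 1, 2), 3), c(TRUE, TRUE, FALSE)),
               "zero control SD")
})

test_that("the 5-SD outlier rule removes exactly the planted violators", {
  set.seed(10)
  Z <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(paste0("S", 1:10), paste0("r", 1:4)))
  Z[abs(Z) > 4.9] <- 0
  Z[3, 2] <- 6      # single ROI at 6 SD
  Z[8, c(1, 4)] <- c(-5.5, 7)
  out <- remove_outliers(Z, threshold = 5)
  expect_equal(out$report$removed, c("S3", "S8"))
  expect_equal(out$report$offending$S3, "r2")
  expect_equal(sort(out$report$offending$S8), c("r1", "r4"))
  expect_equal(nrow(out$z), 8)
  # nothing above threshold -> identity and empty report
  ok <- remove_outliers(Z[-c(3, 8), ], threshold = 5)
  expect_equal(ok$z, Z[-c(3, 8), ])
  expect_length(ok$report$removed, 0)
})

test_that("harmonization is idempotent and removes planted site effects", {
  cfg <- sim_config(n_patients = 150, n_controls = 150, seed = 31)
  cohort <- generate_cohort(cfg)
  h <- harmonize(strip_truth(cohort))
  z <- as.matrix(h$z)
  ctrl <- h$control_mask
  expect_lt(max(abs(colMeans(z[ctrl, ]))), 1e-8)
  expect_lt(max(abs(apply(z[ctrl, ], 2, sd) - 1)), 1e-8)
  # post-harmonization site effect on each ROI is non-significant
  site <- cohort$site[cohort$subject_id %in% rownames(z)]
  pvals <- apply(z, 2, function(col)
    anova(lm(col ~ site))$`Pr(>F)`[1])
  expect_gt(min(pvals), 0.01)
  # re-harmonizing the harmonized cohort (same subjects, same design)
  # approximately reproduces it; ComBat re-estimates its location/scale
  # parameters on signal-bearing data, so only sampling-noise-sized
  # changes remain. The second sign flip is undone for the comparison.
  idx <- match(rownames(z), cohort$subject_id)
  cohort2 <- cohort[idx, ]
  cohort2[, roi_columns()] <- z
  h2 <- harmonize(strip_truth(cohort2), apply_outlier_filter = FALSE)
  delta <- abs(-as.matrix(h2$z) - z)
  expect_lt(mean(delta), 0.15)
})

test_that("harmonization is exactly idempotent when ComBat has nothing to adjust", {
  # single site: residualize is an exact no-op on its own residuals and
  # ComBat is the identity, so a second pass only flips the sign back
  cfg <- sim_config(n_patients = 80, n_controls = 80, seed = 37,
                    site_shift = 0, site_scale = 1)
  cohort <- generate_cohort(cfg)
  h <- harmonize(strip_truth(cohort), apply_outlier_filter = FALSE)
  z <- as.matrix(h$z)
  cohort2 <- cohort
  cohort2[, roi_columns()] <- z
  h2 <- harmonize(strip_truth(cohort2), apply_outlier_filter = FALSE)
  expect_lt(max(abs(-as.matrix(h2$z) - z)), 1e-6)
})
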