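#' Residualize ROI volumes on nuisance covariates
#'
#' Per ROI, an ordinary-least-squares fit of volume on sex, age, the
#' square of age, site and total intracranial volume; residuals are
#' returned. Coefficients are estimated on the pooled sample by default
#' (`controls_only = TRUE` estimates them on controls and applies them to
#' everyone).
#'
#' @param volumes numeric matrix or data frame, subjects x ROIs
#' @param design data frame with columns `sex`, `age`, `site`, `tiv`
#' @param control_mask logical vector marking control subjects (required
#'   when `controls_only = TRUE`)
#' @param controls_only estimate coefficients on controls only
#' @return residual matrix of the same dimensions as `volumes`
#' @export
residualize <- function(volumes, design, control_mask = NULL,
                        controls_only = FALSE) {
  V <- as.matrix(volumes)
  stopifnot(nrow(V) == nrow(design))
  if (anyNA(design[c("sex", "age", "site", "tiv")]))
    stop("covariate design contains missing values")
  design$site <- factor(design$site)
  form <- if (nlevels(design$site) > 1)
    ~ sex + age + I(age^2) + site + tiv else ~ sex + age + I(age^2) + tiv
  X <- model.matrix(form, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (controls_only) {
    if (is.null(control_mask)) stop("control_mask required for controls_only")
    fit <- lm.fit(X[control_mask, , drop = FALSE],
                  V[control_mask, , drop = FALSE])
    res <- V - X %*% fit$coefficients
  } else {
    res <- V - X %*% qr.coef(qrX, V)
  }
  dimnames(res) <- dimnames(V)
  res
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes additive and multiplicative site/scanner effects by the ComBat
#' location/scale model with parametric empirical-Bayes priors, as
#' implemented in the sva package. A single batch is returned unchanged;
#' batches with fewer than two subjects or zero within-batch variance on
#' any ROI are an error.
#'
#' @param x numeric matrix, subjects x ROIs
#' @param batch batch (site) labels, one per subject
#' @return adjusted matrix of the same dimensions
#' @export
combat_adjust <- function(x, batch) {
  X <- as.matrix(x)
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(X)
  tab <- table(batch)
  if (any(tab < 2)) stop("every batch needs at least 2 subjects")
  for (b in levels(batch)) {
    v <- apply(X[batch == b, , drop = FALSE], 2, var)
    if (any(v <= 0))
      stop("batch ", b, " has zero within-batch variance on some ROI")
  }
  out <- t(suppressMessages(
    sva::ComBat(dat = t(X), batch = batch, prior.plots = FALSE)))
  dimnames(out) <- dimnames(X)
  out
}

#' Normative z-scoring relative to the control group
#'
#' Per ROI, `z = (value - control mean) / control SD`, multiplied by -1 so
#' that the z-score increases as regional volume decreases. Normative
#' `center`/`scale` may be supplied explicitly, e.g. when applying a
#' trained normative model to unseen data.
#'
#' @param x adjusted volume matrix, subjects x ROIs
#' @param control_mask logical vector marking control subjects
#' @param center,scale optional known normative mean/SD per ROI; estimated
#'   from controls when `NULL`
#' @param flip multiply by -1 (default TRUE)
#' @return a `zscore_table`: the z matrix with attributes `control_mask`,
#'   `flipped`, `center`, `scale`
#' @export
to_zscores <- function(x, control_mask, center = NULL, scale = NULL,
                       flip = TRUE) {
  X <- as.matrix(x)
  if (is.null(center) || is.null(scale)) {
    if (sum(control_mask) < 2) stop("need at least 2 controls for z-scoring")
    ctrl <- X[control_mask, , drop = FALSE]
    center <- center %||% colMeans(ctrl)
    scale <- scale %||% apply(ctrl, 2, sd)
  }
  if (any(scale <= 0)) stop("zero control SD on some ROI; cannot z-score")
  Z <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  if (flip) Z <- -Z
  structure(Z, class = c("zscore_table", class(Z)),
            control_mask = control_mask, flipped = flip,
            center = center, scale = scale)
}

#' Remove statistical outliers from a z-score table
#'
#' Drops every subject with any regional deviation more than `threshold`
#' SD away from the group-level average (two-sided on the signed z).
#'
#' @param z a `zscore_table` (or plain matrix)
#' @param threshold SD threshold (default 5)
#' @return `list(z, report)` where `report` records removed subject ids,
#'   the offending ROI(s) and the threshold
#' @export
remove_outliers <- function(z, threshold = 5) {
  Z <- as.matrix(z)
  bad <- abs(Z) > threshold
  drop <- rowSums(bad) > 0
  ids <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  report <- list(
    removed = ids[drop],
    offending = lapply(which(drop), function(i) colnames(Z)[bad[i, ]]),
    threshold = threshold)
  names(report$offending) <- ids[drop]
  out <- Z[!drop, , drop = FALSE]
  cm <- attr(z, "control_mask")
  if (!is.null(cm)) {
    out <- structure(out, class = class(z), control_mask = cm[!drop],
                     flipped = attr(z, "flipped"),
                     center = attr(z, "center"), scale = attr(z, "scale"))
  }
  list(z = out, report = report)
}

#' Full harmonization pipeline
#'
#' Fixed composition: residualize on covariates (sex, age, age squared,
#' site, TIV), ComBat batch adjustment across sites, normative z-scoring
#' against controls with the sign flip, then the 5-SD outlier filter.
#' Simulation-truth columns, if present, are stripped before any step.
#'
#' @param cohort a `cohort_table` (or any data frame with the covariate
#'   and ROI columns)
#' @param atlas a [roi_atlas()] naming the ROI columns; by default every
#'   column prefixed `roi_` is treated as an ROI
#' @param controls_only estimate regression coefficients on controls only
#' @param outlier_threshold SD threshold for the outlier filter
#' @param apply_outlier_filter run the outlier step (default TRUE)
#' @param center,scale optional known normative parameters passed to
#'   [to_zscores()]
#' @return list with elements `z` (a `zscore_table`), `control_mask`,
#'   `outliers` (report), `kept` (logical over input rows)
#' @export
harmonize <- function(cohort, atlas = NULL, controls_only = FALSE,
                      outlier_threshold = 5, apply_outlier_filter = TRUE,
                      center = NULL, scale = NULL) {
  cohort <- strip_truth(cohort)
  cols <- if (is.null(atlas)) grep("^roi_", names(cohort), value = TRUE)
          else roi_columns(atlas)
  if (length(cols) == 0 || !all(cols %in% names(cohort)))
    stop("cohort lacks ROI columns",
         if (!is.null(atlas)) paste0(": ",
           paste(setdiff(roi_columns(atlas), names(cohort)),
                 collapse = ", ")))
  V <- as.matrix(cohort[, cols])
  rownames(V) <- cohort$subject_id
  control_mask <- cohort$group == "control"
  design <- cohort[, c("sex", "age", "site", "tiv")]
  res <- residualize(V, design, control_mask, controls_only = controls_only)
  adj <- combat_adjust(res, cohort$site)
  z <- to_zscores(adj, control_mask, center = center, scale = scale)
  kept <- rep(TRUE, nrow(z))
  report <- list(removed = character(0), offending = list(),
                 threshold = outlier_threshold)
  if (apply_outlier_filter) {
    o <- remove_outliers(z, outlier_threshold)
    kept <- !(rownames(V) %in% o$report$removed)
    z <- o$z
    report <- o$report
  }
  list(z = z, control_mask = attr(z, "control_mask"),
       outliers = report, kept = kept)
}
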