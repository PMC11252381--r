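#' Spearman correlates of model stage
#'
#' Spearman correlation between the inferred stage and each measure
#' (regional z-scores, illness duration, symptom scores, ...), with
#' Benjamini-Hochberg false-discovery-rate adjustment across measures.
#'
#' @param stages integer vector of inferred stages
#' @param measures data frame or matrix of measures, one column each
#' @return data frame with columns `measure`, `rho`, `p`, `q`, `n`;
#'   constant measures yield `NA` with a warning
#' @export
stage_correlates <- function(stages, measures) {
  measures <- as.data.frame(measures)
  res <- lapply(names(measures), function(nm) {
    x <- measures[[nm]]
    ok <- complete.cases(stages, x)
    if (sum(ok) < 10) stop("need at least 10 paired observations for ", nm)
    if (sd(x[ok]) == 0) {
      warning("measure ", nm, " is constant; correlation undefined")
      return(data.frame(measure = nm, rho = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    ct <- suppressWarnings(cor.test(stages[ok], x[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(measure = nm, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("measure", "rho", "p", "q", "n")]
}

#' Bin illness duration into early/middle/late stages
#'
#' Default boundary convention: early `<= 2` years, middle `(2, 10]`,
#' late `> 10` (`convention = "caption"`). The strict-early alternative
#' (`"methods"`: early `< 2`, middle `[2, 10]`, late `> 10`) is
#' selectable.
#'
#' @param durations illness durations in years, non-negative
#' @param convention `"caption"` (default) or `"methods"`
#' @return factor with levels `early`, `middle`, `late` (`NA` kept)
#' @export
bin_duration <- function(durations, convention = c("caption", "methods")) {
  convention <- match.arg(convention)
  if (any(durations < 0, na.rm = TRUE)) stop("durations must be non-negative")
  cut_early <- if (convention == "caption") durations <= 2 else durations < 2
  out <- ifelse(cut_early, "early", ifelse(durations <= 10, "middle", "late"))
  factor(out, levels = c("early", "middle", "late"))
}

#' Symptom trajectories across duration bins
#'
#' Within each subtype, a one-way ANOVA of each subscale across the three
#' duration bins; within each bin, a two-sample t-test between subtypes on
#' the subscale residuals after regressing out age, sex and model stage.
#' P-values are two-sided and uncorrected.
#'
#' @param clinical data frame of subscale columns (patients)
#' @param subtype integer subtype labels
#' @param bins factor from [bin_duration()]
#' @param covariates data frame with columns `age`, `sex`
#' @param stage inferred model stage per patient
#' @param min_cell minimum subjects per (subtype, bin) cell (default 3)
#' @return list with `anova` (subtype x subscale F and p) and `contrasts`
#'   (per bin and subscale: adjusted means, t, p, group sizes)
#' @export
symptom_trajectory <- function(clinical, subtype, bins, covariates, stage,
                               min_cell = 3) {
  clinical <- as.data.frame(clinical)
  subtypes <- sort(unique(subtype))
  anova_rows <- list(); contrast_rows <- list()
  for (st in subtypes) {
    for (nm in names(clinical)) {
      idx <- which(subtype == st & !is.na(bins) & !is.na(clinical[[nm]]))
      if (length(idx) < 2 * min_cell ||
          min(table(bins[idx])) < min_cell) {
        warning("cell too small for subtype ", st, ", ", nm, "; skipped")
        next
      }
      fit <- aov(clinical[[nm]][idx] ~ bins[idx])
      a <- anova(fit)
      anova_rows[[length(anova_rows) + 1]] <-
        data.frame(subtype = st, subscale = nm,
                   F = a$`F value`[1], p = a$`Pr(>F)`[1])
    }
  }
  if (length(subtypes) == 2) {
    for (bn in levels(bins)) {
      for (nm in names(clinical)) {
        idx <- which(bins == bn & !is.na(clinical[[nm]]))
        g <- subtype[idx]
        if (length(idx) < 2 * min_cell || min(table(factor(g, subtypes))) <
            min_cell) {
          warning("cell too small for bin ", bn, ", ", nm, "; skipped")
          next
        }
        df <- data.frame(y = clinical[[nm]][idx],
                         age = covariates$age[idx],
                         sex = covariates$sex[idx],
                         stage = stage[idx])
        r <- resid(lm(y ~ age + sex + stage, df))
        tt <- t.test(r[g == subtypes[1]], r[g == subtypes[2]],
                     var.equal = TRUE)
        contrast_rows[[length(contrast_rows) + 1]] <-
          data.frame(bin = bn, subscale = nm,
                     mean1 = mean(r[g == subtypes[1]]),
                     mean2 = mean(r[g == subtypes[2]]),
                     t = unname(tt$statistic), p = tt$p.value,
                     n1 = sum(g == subtypes[1]), n2 = sum(g == subtypes[2]))
      }
    }
  }
  list(anova = do.call(rbind, anova_rows),
       contrasts = do.call(rbind, contrast_rows))
}

#' Inter-subtype contrasts of regional z-scores
#'
#' Per measure: pooled-variance two-sample t-test between the two
#' subtypes, Cohen's d on the pooled SD (sign convention:
#' subtype 1 minus subtype 2), and Holm family-wise-error adjustment
#' across measures.
#'
#' @param z subjects x measures matrix of normative z-scores
#' @param subtype integer subtype labels (two groups)
#' @return data frame with columns `measure`, `mean1`, `mean2`, `t`, `p`,
#'   `p_fwe`, `d`
#' @export
intersubtype_morphometry <- function(z, subtype) {
  Z <- as.matrix(z)
  groups <- sort(unique(subtype))
  if (length(groups) != 2) stop("exactly two subtypes required")
  i1 <- subtype == groups[1]; i2 <- subtype == groups[2]
  if (!any(i1) || !any(i2)) stop("one subtype is empty")
  res <- lapply(seq_len(ncol(Z)), function(j) {
    x <- Z[i1, j]; y <- Z[i2, j]
    tt <- t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    data.frame(measure = colnames(Z)[j] %||% paste0("m", j),
               mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               d = if (sp > 0) (mean(x) - mean(y)) / sp else 0)
  })
  out <- do.call(rbind, res)
  out$p_fwe <- p.adjust(out$p, method = "holm")
  out[, c("measure", "mean1", "mean2", "t", "p", "p_fwe", "d")]
}

#' Generalization of subtyping and staging to unseen subjects
#'
#' Fits the model on a training subset and on the full data; both models
#' assign the unseen subjects, and after label matching the fraction of
#' unseen subjects keeping the same subtype label and the Spearman
#' correlation of their stages are reported.
#'
#' @param Z patients x biomarkers z-score matrix
#' @param train_idx integer indices of the training subset
#' @param K number of subtypes
#' @param spec a [sustain_spec()]
#' @param settings a [sustain_settings()]
#' @param seed integer seed
#' @param full_model optional precomputed full-data `sustain_model`
#' @param mcmc run MCMC refinement in the fits (default TRUE, matching
#'   the main analysis; `FALSE` uses the EM point estimates)
#' @return list with `agreement`, `stage_rho`, `n_unseen`, and the two
#'   models
#' @export
generalization_check <- function(Z, train_idx, K, spec,
                                 settings = sustain_settings(), seed = 1,
                                 full_model = NULL, mcmc = TRUE) {
  Z <- as.matrix(Z)
  unseen <- setdiff(seq_len(nrow(Z)), train_idx)
  if (!length(train_idx)) stop("training subset is empty")
  if (is.null(full_model))
    full_model <- sustain_fit(Z, K, spec, settings,
                              seed = child_seed(seed, "full"), mcmc = mcmc)
  # training on the full data is the full-data model
  train_model <- if (length(unseen) == 0) full_model else
    sustain_fit(Z[train_idx, , drop = FALSE], K, spec, settings,
                seed = child_seed(seed, "train"), mcmc = mcmc)
  target <- if (length(unseen)) Z[unseen, , drop = FALSE] else Z
  a_full <- sustain_assign(target, full_model, spec)
  a_train <- sustain_assign(target, train_model, spec)
  perm <- match_labels(a_full$table$subtype, a_train$table$subtype, K)
  mapped <- perm[a_train$table$subtype]
  list(agreement = mean(mapped == a_full$table$subtype),
       stage_rho = suppressWarnings(
         cor(a_full$table$stage, a_train$table$stage, method = "spearman")),
       n_unseen = nrow(target),
       train_model = train_model, full_model = full_model)
}
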