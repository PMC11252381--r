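#' Hopkins statistic of clustering tendency
#'
#' `m` uniform probe points are drawn over the data's bounding box and `m`
#' real points are sampled; `u_i` and `w_i` are their nearest-real-neighbor
#' distances (each sampled point excluded from its own search).
#' `H = sum(u) / (sum(u) + sum(w))` is about 0.5 for spatially uniform
#' data and approaches 1 for clustered data. The verdict compares H with
#' the `Beta(m, m)` null quantile at the stated confidence level.
#'
#' @param X numeric matrix, subjects x features
#' @param m number of probes (default `ceiling(0.1 * n)`, capped at 100)
#' @param seed integer seed
#' @param level confidence level for the verdict (default 0.90)
#' @return a `hopkins_result`: list with `H`, `m`, `level`, `threshold`,
#'   `clustered`
#' @export
hopkins_statistic <- function(X, m = NULL, seed = 1, level = 0.90) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 observations")
  m <- m %||% min(100L, ceiling(0.1 * n))
  if (m >= n) stop("m must be smaller than n")
  set.seed(seed)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  probes <- sapply(seq_along(lo), function(j) runif(m, lo[j], hi[j]))
  probes <- matrix(probes, nrow = m)
  samp <- sample.int(n, m)
  nn_dist <- function(P, exclude = NULL) {
    vapply(seq_len(nrow(P)), function(i) {
      d2 <- colSums((t(X) - P[i, ])^2)
      if (!is.null(exclude)) d2[exclude[i]] <- Inf
      sqrt(min(d2))
    }, numeric(1))
  }
  u <- nn_dist(probes)
  w <- nn_dist(X[samp, , drop = FALSE], exclude = samp)
  H <- sum(u) / (sum(u) + sum(w))
  threshold <- qbeta(level, m, m)
  structure(list(H = H, m = m, level = level, threshold = threshold,
                 clustered = H > threshold),
            class = "hopkins_result")
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf("Hopkins H = %.4f (m = %d); %sclustered at %.0f%% confidence (threshold %.4f)\n",
              x$H, x$m, if (x$clustered) "" else "not ",
              100 * x$level, x$threshold))
  invisible(x)
}

# all permutations of 1..K (K small)
all_permutations <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(K - 1))
    for (pos in seq_len(K))
      out[[length(out) + 1]] <- append(p, K, after = pos - 1)
  out
}

#' Match subtype labels between two labelings
#'
#' Subtype indices are arbitrary across independent fits; this finds the
#' permutation of `1..K` maximizing total overlap between the two
#' labelings (exhaustive search over the K x K contingency table, exact
#' for the small K used here).
#'
#' @param labels_a,labels_b integer labels in `1..K` over the same subjects
#' @param K number of subtypes
#' @return integer permutation `p`; apply as `p[labels_b]` to align
#'   `labels_b` with `labels_a`
#' @export
match_labels <- function(labels_a, labels_b, K) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must cover the same subjects")
  if (any(c(labels_a, labels_b) < 1) || any(c(labels_a, labels_b) > K))
    stop("labels must lie in 1..K")
  tab <- table(factor(labels_b, levels = 1:K),
               factor(labels_a, levels = 1:K))
  best <- NULL; best_overlap <- -1
  for (p in all_permutations(K)) {
    overlap <- sum(tab[cbind(1:K, p)])
    if (overlap > best_overlap) { best_overlap <- overlap; best <- p }
  }
  as.integer(best)
}

#' Dice consistency of two subtype labelings
#'
#' After label matching, per-subtype Dice is
#' `2 |A_c intersect B_c| / (|A_c| + |B_c|)`; the overall value is the
#' subject-weighted mean of the per-subtype values (equivalently the
#' fraction of subjects keeping the same label). Transition fractions give
#' the share of subjects moving from subtype c to c'.
#'
#' @param labels_a,labels_b integer labels in `1..K`
#' @param K number of subtypes
#' @param match align `labels_b` with [match_labels()] first (default TRUE)
#' @return list with `overall`, `per_subtype`, `transitions` (K x K matrix
#'   of subject fractions), `permutation`
#' @export
dice_consistency <- function(labels_a, labels_b, K, match = TRUE) {
  perm <- seq_len(K)
  if (match) perm <- match_labels(labels_a, labels_b, K)
  b <- perm[labels_b]
  per <- numeric(K)
  w <- numeric(K)
  for (c in seq_len(K)) {
    na <- sum(labels_a == c); nb <- sum(b == c)
    inter <- sum(labels_a == c & b == c)
    if (na + nb == 0) {
      per[c] <- NA_real_
      warning("subtype ", c, " empty in both labelings; Dice undefined")
    } else per[c] <- 2 * inter / (na + nb)
    w[c] <- (na + nb) / 2
  }
  ok <- !is.na(per)
  overall <- sum(per[ok] * w[ok]) / sum(w[ok])
  transitions <- table(factor(labels_a, levels = 1:K),
                       factor(b, levels = 1:K)) / length(labels_a)
  list(overall = overall, per_subtype = per,
       transitions = as.matrix(transitions), permutation = perm)
}

#' Choose the number of subtypes by cross-validated Dice consistency
#'
#' Per repeat, patients are split into two non-overlapping folds and a
#' model hierarchy is fitted on each fold; for every K both fold models
#' label all patients and the two labelings are compared by the Dice
#' coefficient after label matching. The chosen K maximizes the median
#' Dice over repeats (ties toward the smaller K). K = 1 is excluded (its
#' Dice is trivially 1); the Hopkins statistic answers whether clustering
#' exists at all.
#'
#' @param Z patients x biomarkers z-score matrix
#' @param K_range candidate numbers of subtypes (default 2:6)
#' @param n_repeats number of random half-splits (default 10)
#' @param spec a [sustain_spec()]
#' @param settings a [sustain_settings()]
#' @param seed integer seed
#' @param holdout_only label only the held-out fold instead of all
#'   patients (default FALSE)
#' @param debug_identical_folds use the same fold twice (diagnostic; Dice
#'   is then 1 for every K)
#' @return a `dice_curve`: list with `values` (repeats x K matrix),
#'   `median`, `sd`, `chosen_K`
#' @export
select_K <- function(Z, K_range = 2:6, n_repeats = 10, spec,
                     settings = sustain_settings(), seed = 1,
                     holdout_only = FALSE, debug_identical_folds = FALSE) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  K_max <- max(K_range)
  values <- matrix(NA_real_, n_repeats, length(K_range),
                   dimnames = list(NULL, paste0("K", K_range)))
  for (r in seq_len(n_repeats)) {
    set.seed(child_seed(seed, paste0("fold", r)))
    fold1 <- sort(sample.int(n, floor(n / 2)))
    fold2 <- setdiff(seq_len(n), fold1)
    if (debug_identical_folds) fold2 <- fold1
    if (min(length(fold1), length(fold2)) < K_max) {
      warning("fold too small for K = ", K_max, " in repeat ", r)
      next
    }
    seed_a <- child_seed(seed, paste0("fitA", r))
    # identical folds with an identical seed reproduce the same model
    seed_b <- if (debug_identical_folds) seed_a else
      child_seed(seed, paste0("fitB", r))
    h1 <- fit_hierarchy(Z[fold1, , drop = FALSE], K_max, spec, settings,
                        seed = seed_a)
    h2 <- fit_hierarchy(Z[fold2, , drop = FALSE], K_max, spec, settings,
                        seed = seed_b)
    for (j in seq_along(K_range)) {
      K <- K_range[j]
      target <- if (holdout_only) rbind(Z[fold2, , drop = FALSE]) else Z
      la <- sustain_assign(target, h1[[K]], spec)$table$subtype
      lb <- sustain_assign(target, h2[[K]], spec)$table$subtype
      values[r, j] <- dice_consistency(la, lb, K)$overall
    }
  }
  med <- apply(values, 2, median, na.rm = TRUE)
  structure(list(values = values, median = med,
                 sd = apply(values, 2, sd, na.rm = TRUE),
                 K_range = K_range,
                 chosen_K = K_range[which.max(med)]),
            class = "dice_curve")
}

#' @export
print.dice_curve <- function(x, ...) {
  cat("cross-validated Dice consistency:\n")
  print(round(rbind(median = x$median, sd = x$sd), 3))
  cat("chosen K =", x$chosen_K, "\n")
  invisible(x)
}
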