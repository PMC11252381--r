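#' Fitting settings for the event-based model
#'
#' Defaults are scaled for interactive use and testing (5 starts, 10,000
#' MCMC iterations); the full-scale analysis settings are 25 starts and
#' 100,000 iterations.
#'
#' @param n_starts number of random starting points for the
#'   expectation-maximization sequence search
#' @param n_iter Markov chain Monte Carlo iterations
#' @param split_restarts random binary partitions tried per parent subtype
#'   when growing the hierarchy by one subtype
#' @param em_max_iter,em_tol EM outer-loop limits (`em_tol` in absolute
#'   log-likelihood units)
#' @param greedy_max_sweeps cap on greedy repositioning sweeps when
#'   optimizing a sequence to convergence
#' @param em_greedy_sweeps greedy sweeps per EM iteration after the first
#'   (a generalized M-step; convergence is reached over the outer loop)
#' @param assign_thin number of archive draws used when averaging subject
#'   subtype probabilities over the MCMC archive
#' @return a `sustain_settings` list
#' @export
sustain_settings <- function(n_starts = 5, n_iter = 10000,
                             split_restarts = 10, em_max_iter = 10,
                             em_tol = 0.01, greedy_max_sweeps = 50,
                             em_greedy_sweeps = 2, assign_thin = 100) {
  structure(list(n_starts = n_starts, n_iter = n_iter,
                 split_restarts = split_restarts,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 greedy_max_sweeps = greedy_max_sweeps,
                 em_greedy_sweeps = em_greedy_sweeps,
                 assign_thin = assign_thin),
            class = "sustain_settings")
}

# stage log-likelihood matrix (n x (E+1)) for one sequence
stage_loglik_matrix <- function(Z, seq, spec) {
  M <- cpp_expected_matrix(seq$biomarker, seq$z,
                           length(spec$biomarkers), spec$z_max)
  cpp_stage_loglik(as.matrix(Z), M, spec$sigma)
}

# stage-marginal subject log-likelihoods (length n) for one sequence
marginal_loglik <- function(Z, seq, spec) {
  cpp_row_logmeanexp(stage_loglik_matrix(Z, seq, spec))
}

#' Stage-marginal log-likelihood of one subject
#'
#' `log[(1/(E+1)) * sum_k prod_b Normal(z_b; g(seq, k, b), sigma_b^2)]`,
#' the subject's likelihood under a uniform prior over stages `0..E`,
#' computed in log space.
#'
#' @param z_row numeric vector of biomarker z-scores
#' @param seq an `event_sequence`
#' @param spec a [sustain_spec()]
#' @return the log-likelihood, a scalar
#' @export
subject_loglik <- function(z_row, seq, spec = attr(seq, "spec")) {
  if (!all(is.finite(z_row))) stop("z_row must be finite")
  if (length(z_row) != length(spec$biomarkers))
    stop("z_row length must equal the number of biomarkers")
  validate_sequence(seq, spec)
  as.numeric(marginal_loglik(matrix(z_row, 1), seq, spec))
}

#' Total mixture log-likelihood of a fitted model
#'
#' `sum_i log sum_c f_c exp(subject_loglik(z_i, seq_c))`, evaluated with a
#' stable log-sum-exp.
#'
#' @param Z subjects x biomarkers z-score matrix
#' @param model a `sustain_model`
#' @param spec a [sustain_spec()]
#' @return total log-likelihood, a scalar
#' @export
mixture_loglik <- function(Z, model, spec = model$spec) {
  Z <- as.matrix(Z)
  margs <- vapply(model$sequences, function(s) marginal_loglik(Z, s, spec),
                  numeric(nrow(Z)))
  margs <- matrix(margs, nrow = nrow(Z))
  lf <- sweep(margs, 2, log(model$fractions), "+")
  sum(cpp_row_logsumexp(lf))
}

new_sustain_model <- function(sequences, fractions, loglik, spec, settings,
                              seed, archive = NULL) {
  structure(list(sequences = sequences, fractions = fractions,
                 loglik = loglik, spec = spec, settings = settings,
                 seed = seed, archive = archive),
            class = "sustain_model")
}

#' @export
print.sustain_model <- function(x, ...) {
  cat("event-based subtype model: K =", length(x$sequences),
      "| fractions:", paste(round(x$fractions, 3), collapse = "/"),
      "| loglik:", round(x$loglik, 2), "\n")
  if (!is.null(x$archive))
    cat("MCMC archive:", length(x$archive$loglik), "iterations\n")
  invisible(x)
}

# one EM run from given initial sequences. The sequence update is a
# generalized M-step: a bounded number of greedy sweeps per iteration
# (full convergence is reached over the outer iterations). Subjects whose
# responsibility for a subtype is negligible (< 1e-3) are left out of that
# subtype's greedy search; the EM objective itself is always evaluated on
# all subjects.
em_run <- function(Z, init_seqs, init_fracs, spec, settings,
                   max_iter = settings$em_max_iter,
                   first_sweeps = settings$greedy_max_sweeps) {
  n <- nrow(Z)
  K <- length(init_seqs)
  seqs <- init_seqs
  fracs <- init_fracs
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    margs <- vapply(seqs, function(s) marginal_loglik(Z, s, spec), numeric(n))
    margs <- matrix(margs, nrow = n)
    lf <- sweep(margs, 2, log(fracs), "+")
    lse <- cpp_row_logsumexp(lf)
    ll <- sum(lse)
    if (it > 1 && ll - prev < settings$em_tol) break
    prev <- ll
    resp <- exp(lf - as.numeric(lse))
    fracs <- pmax(colMeans(resp), 1e-8)
    fracs <- fracs / sum(fracs)
    sweeps <- if (it == 1) first_sweeps else settings$em_greedy_sweeps
    for (c in seq_len(K)) {
      act <- if (K == 1) seq_len(n) else which(resp[, c] > 1e-3)
      opt <- cpp_opt_sequence(Z[act, , drop = FALSE], resp[act, c],
                              seqs[[c]]$biomarker,
                              seqs[[c]]$z, spec$z_max, spec$sigma,
                              sweeps)
      seqs[[c]] <- event_sequence(opt$ev_bio, opt$ev_z, spec)
    }
  }
  margs <- vapply(seqs, function(s) marginal_loglik(Z, s, spec), numeric(n))
  margs <- matrix(margs, nrow = n)
  lf <- sweep(margs, 2, log(fracs), "+")
  lse <- cpp_row_logsumexp(lf)
  list(sequences = seqs, fractions = fracs, loglik = sum(lse),
       responsibilities = exp(lf - as.numeric(lse)))
}

#' Optimize event sequences by expectation-maximization
#'
#' From each random start: alternate (i) subject responsibilities under the
#' current sequences and fractions, (ii) fraction updates to the mean
#' responsibility, and (iii) per-subtype greedy single-event repositioning
#' that accepts moves raising the responsibility-weighted likelihood, until
#' no improving move remains. The best of `n_starts` runs by total
#' log-likelihood is returned.
#'
#' @param Z subjects x biomarkers z-score matrix (patients only)
#' @param K number of subtypes
#' @param spec a [sustain_spec()]
#' @param settings a [sustain_settings()]
#' @param seed integer seed
#' @param init optional list of `K` initial `event_sequence`s; when given,
#'   a single EM run is started from them
#' @param init_fractions optional initial mixture fractions
#' @return a `sustain_model` (no MCMC archive)
#' @export
optimize_sequences_em <- function(Z, K, spec, settings = sustain_settings(),
                                  seed = 1, init = NULL,
                                  init_fractions = NULL) {
  Z <- as.matrix(Z)
  if (K > nrow(Z)) stop("K exceeds the number of subjects")
  if (K < 1) stop("K must be at least 1")
  set.seed(seed)
  best <- NULL
  n_starts <- if (is.null(init)) settings$n_starts else 1L
  for (s in seq_len(n_starts)) {
    seqs <- if (is.null(init)) replicate(K, random_sequence(spec),
                                         simplify = FALSE) else init
    fracs <- init_fractions %||% rep(1 / K, K)
    run <- em_run(Z, seqs, fracs, spec, settings)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  new_sustain_model(best$sequences, best$fractions, best$loglik, spec,
                    settings, seed)
}

# encode sequence as event ids for compact archiving
seq_to_ids <- function(seq, spec) {
  W <- length(spec$waypoints)
  (seq$biomarker - 1L) * W + match(seq$z, spec$waypoints)
}
ids_to_seq <- function(ids, spec) {
  W <- length(spec$waypoints)
  event_sequence((ids - 1L) %/% W + 1L, spec$waypoints[(ids - 1L) %% W + 1L],
                 spec)
}

#' Refine a model by Metropolis-Hastings over event orderings
#'
#' Each iteration removes one event of one subtype's sequence and
#' reinserts it uniformly among the positions preserving the
#' within-biomarker threshold order; the move is accepted with probability
#' `min(1, exp(delta log-likelihood))`. The full archive of visited
#' sequences and log-likelihoods is retained and the returned model's
#' sequences are the maximum-likelihood sample.
#'
#' @param Z subjects x biomarkers z-score matrix
#' @param model an initialized `sustain_model`
#' @param spec a [sustain_spec()]
#' @param n_iter number of iterations (default from model settings)
#' @param seed integer seed
#' @return the refined `sustain_model` carrying an `archive` with per-
#'   subtype event-id matrices (`n_iter` x `E`) and a log-likelihood trace
#' @export
mcmc_sequences <- function(Z, model, spec = model$spec,
                           n_iter = model$settings$n_iter, seed = 1) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  Z <- as.matrix(Z)
  set.seed(seed)
  K <- length(model$sequences)
  E <- spec$n_events
  W <- length(spec$waypoints)
  B <- length(spec$biomarkers)
  # event id table: id = (biomarker - 1) * W + waypoint index
  bio_of <- rep(seq_len(B), each = W)
  z_of <- rep(spec$waypoints, B)
  init <- do.call(rbind, lapply(model$sequences,
                                function(s) seq_to_ids(s, spec)))
  res <- cpp_mcmc(Z, init, bio_of, z_of, model$fractions, spec$z_max,
                  spec$sigma, as.integer(n_iter))
  arch_ll <- as.numeric(res$loglik)
  ml <- which.max(arch_ll)
  ml_seqs <- lapply(seq_len(K),
                    function(c) ids_to_seq(res$ids[[c]][ml, ], spec))
  new_sustain_model(ml_seqs, model$fractions, arch_ll[ml], spec,
                    model$settings, seed,
                    archive = list(ids = res$ids, loglik = arch_ll,
                                   ml_index = ml,
                                   acceptance = res$n_accept / n_iter))
}

# grow a (C-1)-subtype model to C subtypes by splitting one parent.
# Candidate partitions of the parent's subjects: (i) k-means on the
# subjects' within-row deficit ranks -- the rank profile encodes the
# *order* in which regions are affected, independent of stage, which is
# exactly what distinguishes subtypes and breaks the symmetric blend
# optimum that purely random partitions converge to; (ii)
# `split_restarts` random binary partitions. Candidates are scored by a
# short EM run; only the best gets the full EM refinement.
split_step <- function(Z, model, spec, settings) {
  n <- nrow(Z)
  K <- length(model$sequences)
  margs <- vapply(model$sequences, function(s) marginal_loglik(Z, s, spec),
                  numeric(n))
  margs <- matrix(margs, nrow = n)
  lf <- sweep(margs, 2, log(model$fractions), "+")
  hard <- max.col(lf, ties.method = "first")
  best <- NULL
  for (parent in seq_len(K)) {
    idx <- which(hard == parent)
    if (length(idx) < 4) next
    parts <- replicate(settings$split_restarts,
                       sample(rep_len(c(TRUE, FALSE), length(idx))),
                       simplify = FALSE)
    km <- tryCatch(
      kmeans(t(apply(Z[idx, , drop = FALSE], 1, rank)), 2, nstart = 5),
      error = function(e) NULL)
    if (!is.null(km) && min(km$size) >= 2)
      parts <- c(list(km$cluster == 1), parts)
    for (r in seq_along(parts)) {
      part <- parts[[r]]
      halves <- list(idx[part], idx[!part])
      # the k-means candidate gets fresh random child sequences and a
      # full greedy fit; random partitions start from the parent
      from_km <- !is.null(km) && r == 1 && min(km$size) >= 2
      child <- lapply(halves, function(h) {
        init <- if (from_km) random_sequence(spec)
                else model$sequences[[parent]]
        opt <- cpp_opt_sequence(as.matrix(Z[h, , drop = FALSE]),
                                rep(1, length(h)),
                                init$biomarker, init$z,
                                spec$z_max, spec$sigma,
                                if (from_km) 12L else 5L)
        event_sequence(opt$ev_bio, opt$ev_z, spec)
      })
      seqs <- c(model$sequences[-parent], child)
      f_par <- model$fractions[parent]
      fracs <- c(model$fractions[-parent],
                 f_par * c(mean(part), 1 - mean(part)))
      run <- em_run(Z, seqs, fracs, spec, settings, max_iter = 2,
                    first_sweeps = settings$em_greedy_sweeps)
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  }
  if (is.null(best)) stop("no parent subtype large enough to split")
  refined <- em_run(Z, best$sequences, best$fractions, spec, settings)
  new_sustain_model(refined$sequences, refined$fractions, refined$loglik,
                    spec, settings, NA_integer_)
}

#' Fit models for K = 1..K_max by hierarchical splitting
#'
#' Fits the single-subtype model by multi-start EM, then grows the
#' hierarchy one subtype at a time: each existing subtype is tentatively
#' split (random binary partitions of its assigned subjects, each half's
#' sequence re-optimized, the whole model EM-refined on all subjects) and
#' the split giving the best full-data likelihood is kept.
#'
#' @inheritParams optimize_sequences_em
#' @param K_max largest number of subtypes
#' @return list of `sustain_model`s indexed by K
#' @export
fit_hierarchy <- function(Z, K_max, spec, settings = sustain_settings(),
                          seed = 1) {
  Z <- as.matrix(Z)
  models <- vector("list", K_max)
  models[[1]] <- optimize_sequences_em(Z, 1, spec, settings,
                                       seed = child_seed(seed, "em1"))
  if (K_max > 1) {
    for (C in 2:K_max) {
      set.seed(child_seed(seed, paste0("split", C)))
      models[[C]] <- split_step(Z, models[[C - 1]], spec, settings)
    }
  }
  models
}

#' Fit the K-subtype event-based model
#'
#' Hierarchical EM construction up to `K` subtypes followed by MCMC
#' refinement of the final model.
#'
#' @inheritParams optimize_sequences_em
#' @param mcmc run the MCMC refinement stage (default TRUE)
#' @return a fitted `sustain_model` (with archive when `mcmc = TRUE`)
#' @export
sustain_fit <- function(Z, K, spec, settings = sustain_settings(), seed = 1,
                        mcmc = TRUE) {
  models <- fit_hierarchy(Z, K, spec, settings, seed)
  model <- models[[K]]
  if (mcmc)
    model <- mcmc_sequences(Z, model, spec, settings$n_iter,
                            seed = child_seed(seed, "mcmc"))
  model$seed <- seed
  model
}

#' Assign subjects to subtypes and stages
#'
#' Subtype probabilities are proportional to
#' `f_c * exp(subject_loglik under seq_c)`, averaged over a thinned MCMC
#' archive when one is present. The hard label is the argmax (ties toward
#' the lower index); the stage is the maximum-likelihood stage within the
#' hard subtype under the model's maximum-likelihood sequences (ties
#' toward the smaller stage).
#'
#' @param Z subjects x biomarkers z-score matrix
#' @param model a fitted `sustain_model`
#' @param spec a [sustain_spec()]
#' @return a `sustain_assignment`: list with `table` (data frame of hard
#'   subtype and stage), `prob` (subjects x K), and `stage_posterior`
#'   (subjects x (E+1), under the hard subtype)
#' @export
sustain_assign <- function(Z, model, spec = model$spec) {
  if (is.null(model$sequences)) stop("model has not been fitted")
  Z <- as.matrix(Z)
  n <- nrow(Z)
  K <- length(model$sequences)
  draws <- list(model$sequences)
  if (!is.null(model$archive)) {
    n_iter <- length(model$archive$loglik)
    take <- unique(round(seq(1, n_iter,
                             length.out = min(model$settings$assign_thin,
                                              n_iter))))
    draws <- lapply(take, function(it)
      lapply(seq_len(K), function(c)
        ids_to_seq(model$archive$ids[[c]][it, ], spec)))
  }
  prob <- matrix(0, n, K)
  for (dr in draws) {
    margs <- vapply(dr, function(s) marginal_loglik(Z, s, spec), numeric(n))
    margs <- matrix(margs, nrow = n)
    lf <- sweep(margs, 2, log(model$fractions), "+")
    prob <- prob + exp(lf - as.numeric(cpp_row_logsumexp(lf)))
  }
  prob <- prob / length(draws)
  hard <- max.col(prob, ties.method = "first")
  E <- spec$n_events
  stage_post <- matrix(0, n, E + 1)
  stage <- integer(n)
  for (c in seq_len(K)) {
    idx <- which(hard == c)
    if (!length(idx)) next
    L <- stage_loglik_matrix(Z[idx, , drop = FALSE], model$sequences[[c]],
                             spec)
    P <- exp(L - as.numeric(cpp_row_logsumexp(L)))
    stage_post[idx, ] <- P
    stage[idx] <- max.col(P, ties.method = "first") - 1L
  }
  structure(list(table = data.frame(subject = rownames(Z) %||% seq_len(n),
                                    subtype = hard, stage = stage),
                 prob = prob, stage_posterior = stage_post),
            class = "sustain_assignment")
}

#' @export
print.sustain_assignment <- function(x, ...) {
  cat("subject assignment:", nrow(x$table), "subjects,",
      ncol(x$prob), "subtypes\n")
  print(table(subtype = x$table$subtype))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Sequences are written as ordered (biomarker name, threshold) pairs,
#' with mixture fractions and the settings snapshot. The MCMC archive is
#' not serialized.
#'
#' @param model a `sustain_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_json <- function(model, path) {
  spec <- model$spec
  obj <- list(
    K = length(model$sequences),
    fractions = model$fractions,
    loglik = model$loglik,
    sequences = lapply(model$sequences, function(s)
      data.frame(biomarker = spec$biomarkers[s$biomarker], z = s$z)),
    spec = list(biomarkers = spec$biomarkers, waypoints = spec$waypoints,
                z_max = spec$z_max, sigma = spec$sigma),
    settings = unclass(model$settings),
    seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
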