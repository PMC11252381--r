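#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale terms
#' @return log(sum(exp(x))) computed without overflow
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a child seed from a master seed
#'
#' Every random stage of the pipeline draws its own seed deterministically
#' from one master seed, so stages can be re-run in isolation.
#'
#' @param seed master seed (integer)
#' @param stage character tag of the stage
#' @return an integer seed below 2^31
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483629L)
}

# first index of the maximum (ties resolved toward the lower index)
which_max_first <- function(x) which.max(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
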