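#' Model specification for the z-score event-based model
#'
#' An event is a biomarker crossing a z-score waypoint. With `B` biomarkers
#' and `W` waypoints each, a subtype's trajectory is an ordering of the
#' `E = B * W` events. Between waypoints the expected z-score rises
#' linearly with stage, ending at `z_max` at the final stage.
#'
#' @param biomarkers character vector of biomarker names (default: the
#'   17-region atlas)
#' @param waypoints strictly increasing z-score thresholds used as severity
#'   waypoints (default `c(1, 2, 3)`; set to `1` for a single-waypoint
#'   model with one event per biomarker)
#' @param z_max maximum z-score reached at the final stage, scalar or one
#'   per biomarker (default 5; a stricter replication setting uses 4)
#' @param sigma measurement noise SD per biomarker in z units (default 1,
#'   appropriate for normative z-score inputs)
#' @return an object of class `sustain_spec`
#' @export
sustain_spec <- function(biomarkers = default_roi_names(),
                         waypoints = c(1, 2, 3),
                         z_max = 5,
                         sigma = 1) {
  B <- length(biomarkers)
  if (any(diff(waypoints) <= 0)) stop("waypoints must be strictly increasing")
  z_max <- rep_len(z_max, B)
  sigma <- rep_len(sigma, B)
  if (any(z_max < max(waypoints))) stop("z_max must be >= the last waypoint")
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(list(biomarkers = as.character(biomarkers),
                 waypoints = as.numeric(waypoints),
                 z_max = as.numeric(z_max),
                 sigma = as.numeric(sigma),
                 n_events = B * length(waypoints)),
            class = "sustain_spec")
}

#' @export
print.sustain_spec <- function(x, ...) {
  cat("z-score event model: ", length(x$biomarkers), " biomarkers x ",
      length(x$waypoints), " waypoints (z = ",
      paste(x$waypoints, collapse = ", "), ") = ", x$n_events,
      " events; z_max = ", x$z_max[1], "\n", sep = "")
  invisible(x)
}

#' Construct an event sequence
#'
#' @param biomarker character (names) or integer (indices into
#'   `spec$biomarkers`) identifying the biomarker of each event, in order
#' @param z the z-score waypoint crossed by each event
#' @param spec a [sustain_spec()]
#' @return an `event_sequence`: data frame with columns `biomarker`
#'   (integer index), `z`, and the spec attached as an attribute
#' @export
event_sequence <- function(biomarker, z, spec) {
  if (is.character(biomarker)) {
    biomarker <- match(biomarker, spec$biomarkers)
    if (anyNA(biomarker)) stop("unknown biomarker name in sequence")
  }
  seq <- structure(data.frame(biomarker = as.integer(biomarker),
                              z = as.numeric(z)),
                   class = c("event_sequence", "data.frame"),
                   spec = spec)
  validate_sequence(seq, spec)
  seq
}

#' Validate an event sequence against a model specification
#'
#' Checks that every (biomarker, waypoint) pair appears exactly once and
#' that, within each biomarker, waypoints appear in increasing order.
#'
#' @param seq an `event_sequence`
#' @param spec a [sustain_spec()]
#' @return `seq`, invisibly; errors if invalid
#' @export
validate_sequence <- function(seq, spec = attr(seq, "spec")) {
  B <- length(spec$biomarkers)
  if (nrow(seq) != spec$n_events)
    stop("sequence must contain all ", spec$n_events, " events")
  key <- paste(seq$biomarker, seq$z)
  expected <- paste(rep(seq_len(B), each = length(spec$waypoints)),
                    rep(spec$waypoints, B))
  if (!setequal(key, expected) || anyDuplicated(key))
    stop("each (biomarker, waypoint) pair must appear exactly once")
  for (b in seq_len(B)) {
    zs <- seq$z[seq$biomarker == b]
    if (any(diff(zs) <= 0))
      stop("waypoints of biomarker ", spec$biomarkers[b],
           " must appear in increasing order")
  }
  invisible(seq)
}

#' Draw a uniformly random valid event sequence
#'
#' Events are placed by a random permutation; the waypoints of each
#' biomarker are then assigned to its occupied positions in increasing
#' order, which yields a uniform draw over valid sequences.
#'
#' @param spec a [sustain_spec()]
#' @return an `event_sequence`
#' @export
random_sequence <- function(spec) {
  B <- length(spec$biomarkers)
  W <- length(spec$waypoints)
  bio <- sample(rep(seq_len(B), each = W))
  z <- numeric(spec$n_events)
  for (b in seq_len(B)) z[bio == b] <- spec$waypoints
  event_sequence(bio, z, spec)
}

#' Expected z-score surface of a sequence
#'
#' Piecewise-linear interpolation through the anchors (stage 0, z 0), each
#' of the biomarker's waypoint positions, and (final stage, z_max); the
#' z_max anchor is dropped when the biomarker's last waypoint already sits
#' at the final stage.
#'
#' @param seq an `event_sequence`
#' @param spec a [sustain_spec()]
#' @return matrix of dim `(n_events + 1) x n_biomarkers`; row `k + 1` holds
#'   the expected z-scores at stage `k`
#' @export
expected_matrix <- function(seq, spec = attr(seq, "spec")) {
  M <- cpp_expected_matrix(seq$biomarker, seq$z,
                           length(spec$biomarkers), spec$z_max)
  dimnames(M) <- list(stage = 0:spec$n_events, biomarker = spec$biomarkers)
  M
}

#' Expected z-score of one biomarker at one stage
#'
#' @param seq an `event_sequence`
#' @param stage integer stage in `0..n_events`
#' @param biomarker biomarker name or index
#' @param spec a [sustain_spec()]
#' @return the expected z-score, a scalar
#' @export
expected_value <- function(seq, stage, biomarker, spec = attr(seq, "spec")) {
  validate_sequence(seq, spec)
  if (stage < 0 || stage > spec$n_events) stop("stage out of range")
  if (is.character(biomarker)) biomarker <- match(biomarker, spec$biomarkers)
  expected_matrix(seq, spec)[stage + 1, biomarker]
}

# pretty-print: positions of the first few events
#' @export
print.event_sequence <- function(x, n = 6, ...) {
  spec <- attr(x, "spec")
  cat("event sequence over", length(spec$biomarkers), "biomarkers;",
      nrow(x), "events. First", n, ":\n")
  lab <- paste0(spec$biomarkers[x$biomarker], " (z=", x$z, ")")
  cat(" ", paste(head(lab, n), collapse = " -> "), "...\n")
  invisible(x)
}
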