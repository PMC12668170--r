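# Rule-based baseline segmenters and the reference-standard expiratory
# candidate algorithm. The published derivative-backtracking heuristic's
# source is not available; "the derivative began to change" is pinned down
# as a sign change of the first difference or a drop of its magnitude below
# `derivative_eps`, exposed as a parameter.

#' Parameters of the rule-based segmenters
#'
#' @param insp_flow_threshold Flow level (L/min) whose exceedance anchors
#'   inspiratory-onset backtracking (default 12).
#' @param exp_flow_threshold Flow level (L/min) whose undershoot anchors
#'   expiratory-onset search (default -5).
#' @param exp_persistence How long flow must remain negative after the
#'   anchor for it to count, in seconds (default 0.025; "at least 25 ms" is
#'   a lower bound, so the sample count is rounded up).
#' @param derivative_eps Plateau tolerance on the first difference of flow,
#'   in L/min per sample (default 0.5).
#' @return An object of class `heuristic_params`.
#' @export
heuristic_params <- function(insp_flow_threshold = 12, exp_flow_threshold = -5,
                             exp_persistence = 0.025, derivative_eps = 0.5) {
  stopifnot(insp_flow_threshold > 0, exp_flow_threshold < 0,
            exp_persistence > 0, derivative_eps >= 0)
  structure(list(insp_flow_threshold = insp_flow_threshold,
                 exp_flow_threshold = exp_flow_threshold,
                 exp_persistence = exp_persistence,
                 derivative_eps = derivative_eps),
            class = "heuristic_params")
}

# Unvalidated annotation constructor for rule outputs that deliberately
# carry no pairing constraint (the zero-crossing rule is faithful to its
# published naivety and may emit several expiratory onsets per breath).
new_raw_annotation <- function(insp, expo) {
  structure(list(insp_onsets = as.integer(insp), exp_onsets = as.integer(expo),
                 breath_types = NULL),
            class = "onset_annotation")
}

#' Zero-crossing baseline segmenter
#'
#' Labels an inspiratory onset wherever flow crosses from negative to
#' non-negative and an expiratory onset wherever it crosses from positive to
#' non-positive. The crossing is assigned to the first sample on the new
#' sign's side; exact zeros count with the non-negative side. No pairing
#' constraint or debouncing is applied, faithful to the published rule, so
#' noisy flow oscillating around zero emits one onset per sign change.
#'
#' @param record A [vent_record()].
#' @return An `onset_annotation` (unvalidated pairing: the rule may emit
#'   several expiratory onsets per breath).
#' @export
zero_crossing_segment <- function(record) {
  stopifnot(inherits(record, "vent_record"))
  f <- record$flow
  n <- length(f)
  if (n < 2L) stop("record must have at least 2 samples", call. = FALSE)
  prev <- f[-n]; cur <- f[-1]
  insp <- which(prev < 0 & cur >= 0) + 1L
  expo <- which(prev > 0 & cur <= 0) + 1L
  new_raw_annotation(insp, expo)
}

# Maximal runs of a logical vector; returns matrix with columns start, end.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Derivative-backtracking inspiratory onsets
#'
#' For each maximal run of samples with flow above `insp_flow_threshold`,
#' steps backward from the run's first sample while the first difference of
#' flow keeps the sign it had there and its magnitude stays above
#' `derivative_eps`; the onset is placed where the derivative "began to
#' change" (sign flip or plateau).
#'
#' @param record A [vent_record()].
#' @param params A [heuristic_params()].
#' @return Sorted integer vector of inspiratory onset sample indices.
#' @export
derivative_backtrack_insp <- function(record, params = heuristic_params()) {
  stopifnot(inherits(record, "vent_record"))
  f <- record$flow
  n <- length(f)
  if (n < 3L) stop("record must have at least 3 samples", call. = FALSE)
  d <- c(NA_real_, diff(f)) # d[i] = f[i] - f[i-1]
  runs <- logical_runs(f > params$insp_flow_threshold)
  onsets <- integer(0)
  for (r in seq_len(nrow(runs))) {
    i <- runs[r, "start"]
    if (i == 1L) { onsets <- c(onsets, 1L); next }
    s <- sign(d[i])
    while (i > 1L && !is.na(d[i]) && sign(d[i]) == s &&
           abs(d[i]) > params$derivative_eps) {
      i <- i - 1L
    }
    onsets <- c(onsets, i)
  }
  sort(unique(onsets))
}

#' Derivative-backtracking expiratory onsets
#'
#' After each inspiratory onset, searches forward for the first sample with
#' flow below `exp_flow_threshold` that stays negative for at least
#' `exp_persistence` seconds, then steps backward to the nearest earlier
#' sample where flow is non-negative or its first difference has plateaued
#' (magnitude at or below `derivative_eps`). At most one expiratory onset is
#' produced per inspiratory interval, strictly inside it.
#'
#' @param record A [vent_record()].
#' @param insp_onsets Sorted inspiratory onset indices anchoring the search.
#' @param params A [heuristic_params()].
#' @return Sorted integer vector of expiratory onset sample indices.
#' @export
derivative_backtrack_exp <- function(record, insp_onsets,
                                     params = heuristic_params()) {
  stopifnot(inherits(record, "vent_record"))
  f <- record$flow
  n <- length(f)
  insp_onsets <- sort(as.integer(insp_onsets))
  if (!length(insp_onsets)) return(integer(0))
  m <- as.integer(ceiling(params$exp_persistence * record$sample_rate))
  d <- c(NA_real_, diff(f))
  bounds <- c(insp_onsets, n + 1L)
  onsets <- integer(0)
  for (k in seq_along(insp_onsets)) {
    lo <- insp_onsets[k] + 1L
    hi <- bounds[k + 1L] - 1L
    if (lo > hi) next
    found <- NA_integer_
    for (j in lo:hi) {
      if (f[j] < params$exp_flow_threshold) {
        tail_idx <- (j + 1L):min(n, j + m)
        if (j + 1L <= n && all(f[tail_idx] < 0)) { found <- j; break }
      }
    }
    if (is.na(found)) next
    i <- found
    while (i > insp_onsets[k] + 1L &&
           !(f[i - 1L] >= 0 || abs(d[i - 1L]) <= params$derivative_eps)) {
      i <- i - 1L
    }
    onset <- i - 1L
    if (onset > insp_onsets[k] && onset < bounds[k + 1L])
      onsets <- c(onsets, onset)
  }
  sort(unique(onsets))
}

#' Convenience wrapper: full derivative-backtracking segmentation
#'
#' @inheritParams derivative_backtrack_insp
#' @return An `onset_annotation` with backtracked inspiratory and expiratory
#'   onsets.
#' @export
derivative_backtrack_segment <- function(record, params = heuristic_params()) {
  insp <- derivative_backtrack_insp(record, params)
  expo <- derivative_backtrack_exp(record, insp, params)
  new_raw_annotation(insp, expo)
}

#' Reference-standard expiratory onset candidates
#'
#' Within each inspiratory interval, finds the maximal contiguous
#' positive-flow segment with the largest trapezoidal area and returns the
#' first positive-to-non-positive zero crossing after it. This is the
#' algorithm used to seed the reference standard's expiratory labels before
#' expert review.
#'
#' @param record A [vent_record()].
#' @param insp_onsets Sorted inspiratory onset indices (at least one).
#' @return Sorted integer vector of candidate expiratory onset indices;
#'   intervals without positive flow contribute no candidate.
#' @export
reference_exp_candidates <- function(record, insp_onsets) {
  stopifnot(inherits(record, "vent_record"))
  f <- record$flow
  n <- length(f)
  insp_onsets <- sort(as.integer(insp_onsets))
  if (!length(insp_onsets)) stop("at least one inspiratory onset required", call. = FALSE)
  bounds <- c(insp_onsets, n + 1L)
  out <- integer(0)
  for (k in seq_along(insp_onsets)) {
    lo <- insp_onsets[k]; hi <- bounds[k + 1L] - 1L
    seg <- f[lo:hi]
    runs <- logical_runs(seg > 0)
    if (!nrow(runs)) next
    areas <- vapply(seq_len(nrow(runs)), function(r) {
      v <- seg[runs[r, "start"]:runs[r, "end"]]
      if (length(v) < 2L) return(v / 2) # single-sample lobe: triangle-ish sliver
      sum((v[-1] + v[-length(v)]) / 2)
    }, numeric(1))
    best <- which.max(areas)
    cross <- lo + runs[best, "end"] # first sample on the non-positive side
    if (cross <= hi && f[cross] <= 0)
      out <- c(out, cross)
  }
  sort(unique(out))
}
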