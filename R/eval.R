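# Tolerance-window event matching and segmentation metrics. Matching is
# one-to-one, greedy in increasing absolute offset with ties broken toward
# the earlier reference event; an exhaustive optimal-assignment mode
# (maximum cardinality, then minimum total offset) is provided as an oracle
# for small instances. The two rules coincide whenever reference events are
# separated by more than twice the tolerance, which holds for breaths
# (>= ~1 s apart) matched at 0.1 s.

#' Match predicted onset events to a reference standard
#'
#' @param reference Sorted integer vector of reference event sample indices.
#' @param predicted Sorted integer vector of predicted event sample indices.
#' @param tolerance Maximum absolute offset, in samples, for a pair to
#'   match (inclusive). `0` gives exact-timepoint matching.
#' @param method `"greedy"` (default): pairs accepted in increasing
#'   absolute offset, ties toward the earlier reference event.
#'   `"optimal"`: exhaustive maximum-cardinality, minimum-total-offset
#'   assignment (small instances only; intended as a test oracle).
#' @return An object of class `event_match`: counts `tp`, `fp`, `fn`, a
#'   `matches` data frame (`ref`, `pred`, `offset = pred - ref`), and the
#'   tolerance.
#' @export
match_events <- function(reference, predicted, tolerance,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  reference <- as.integer(reference); predicted <- as.integer(predicted)
  stopifnot(!is.unsorted(reference), !is.unsorted(predicted), tolerance >= 0)
  nr <- length(reference); np <- length(predicted)
  empty <- data.frame(ref = integer(0), pred = integer(0), offset = integer(0))
  if (nr == 0L || np == 0L) {
    return(structure(list(tp = 0L, fp = np, fn = nr, matches = empty,
                          tolerance = tolerance, n_ref = nr, n_pred = np),
                     class = "event_match"))
  }
  # candidate pairs: for each predicted event, the compatible reference
  # events form a contiguous range of the sorted reference list
  lo <- findInterval(predicted - tolerance - 0.5, reference) + 1L
  hi <- findInterval(predicted + tolerance + 0.5, reference)
  cand_p <- rep.int(seq_len(np), pmax(hi - lo + 1L, 0L))
  cand_r <- unlist(lapply(seq_len(np), function(j)
    if (hi[j] >= lo[j]) lo[j]:hi[j] else integer(0)))
  if (!length(cand_p)) {
    return(structure(list(tp = 0L, fp = np, fn = nr, matches = empty,
                          tolerance = tolerance, n_ref = nr, n_pred = np),
                     class = "event_match"))
  }
  off <- predicted[cand_p] - reference[cand_r]

  if (method == "greedy") {
    ord <- order(abs(off), cand_r, cand_p)
    used_r <- logical(nr); used_p <- logical(np)
    keep <- integer(0)
    for (i in ord) {
      r <- cand_r[i]; p <- cand_p[i]
      if (!used_r[r] && !used_p[p]) {
        used_r[r] <- TRUE; used_p[p] <- TRUE
        keep <- c(keep, i)
      }
    }
  } else {
    keep <- optimal_assignment(cand_r, cand_p, off, nr, np)
  }
  keep <- keep[order(cand_r[keep])]
  matches <- data.frame(ref = reference[cand_r[keep]],
                        pred = predicted[cand_p[keep]],
                        offset = off[keep])
  tp <- nrow(matches)
  structure(list(tp = tp, fp = np - tp, fn = nr - tp, matches = matches,
                 tolerance = tolerance, n_ref = nr, n_pred = np),
            class = "event_match")
}

# Exhaustive maximum-cardinality, minimum-total-|offset| assignment over the
# candidate pair list. Exponential; oracle use only.
optimal_assignment <- function(cand_r, cand_p, off, nr, np) {
  by_ref <- split(seq_along(cand_r), cand_r)
  refs <- as.integer(names(by_ref))
  best <- list(card = -1L, cost = Inf, keep = integer(0))
  recurse <- function(ri, used_p, keep, cost) {
    if (ri > length(refs)) {
      card <- length(keep)
      if (card > best$card || (card == best$card && cost < best$cost))
        best <<- list(card = card, cost = cost, keep = keep)
      return(invisible())
    }
    # skip this reference
    recurse(ri + 1L, used_p, keep, cost)
    for (i in by_ref[[ri]]) {
      p <- cand_p[i]
      if (!used_p[p]) {
        used_p[p] <- TRUE
        recurse(ri + 1L, used_p, c(keep, i), cost + abs(off[i]))
        used_p[p] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), integer(0), 0)
  best$keep
}

#' @export
print.event_match <- function(x, ...) {
  cat(sprintf("<event_match> tp=%d fp=%d fn=%d (tolerance %d samples)\n",
              x$tp, x$fp, x$fn, x$tolerance))
  invisible(x)
}

#' Precision, recall and F1 from an event match
#'
#' F1 is the harmonic mean of precision (positive predictive value) and
#' recall (sensitivity). Empty denominators yield 0 with a warning.
#'
#' @param result An [match_events()] result, or any list with `tp`, `fp`,
#'   `fn` counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf1 <- function(result) {
  tp <- result$tp; fp <- result$fp; fn <- result$fn
  if (tp + fp == 0L || tp + fn == 0L || tp == 0L) {
    if (tp + fp == 0L || tp + fn == 0L)
      warning("empty denominator in precision/recall; reporting 0", call. = FALSE)
    p <- if (tp + fp > 0L) tp / (tp + fp) else 0
    r <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    return(c(precision = p, recall = r, f1 = f))
  }
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  c(precision = p, recall = r, f1 = 2 * p * r / (p + r))
}

#' Breath-type-stratified segmentation metrics
#'
#' Assigns every reference and predicted event to the stratum of its
#' enclosing reference breath (`normal`, `pva`, or `artifact`; the finer
#' `double_trigger` / `stacked` labels fold into `pva`), matches within each
#' stratum at the given tolerance, and reports per-stratum and pooled
#' precision/recall/F1 for each onset type.
#'
#' @param reference An [onset_annotation()] carrying `breath_types`.
#' @param predicted An [onset_annotation()] (or list with `insp_onsets`,
#'   `exp_onsets`).
#' @param tolerance Matching tolerance in samples.
#' @return A data frame with one row per (stratum, onset type), including a
#'   pooled `"all"` stratum.
#' @export
stratified_eval <- function(reference, predicted, tolerance) {
  if (is.null(reference$breath_types))
    stop("reference annotation carries no breath_types", call. = FALSE)
  fold <- function(bt) ifelse(bt %in% c("double_trigger", "stacked", "pva"),
                              "pva", bt)
  strata_of_breath <- fold(reference$breath_types)
  insp_r <- reference$insp_onsets
  breath_of <- function(idx) pmax(findInterval(idx, insp_r), 1L)
  rows <- list()
  for (otype in c("insp", "exp")) {
    ref_ev <- if (otype == "insp") reference$insp_onsets else reference$exp_onsets
    pred_ev <- if (otype == "insp") predicted$insp_onsets else predicted$exp_onsets
    ref_strat <- strata_of_breath[breath_of(ref_ev)]
    pred_strat <- strata_of_breath[breath_of(pred_ev)]
    for (s in c("all", unique(strata_of_breath))) {
      r <- if (s == "all") ref_ev else ref_ev[ref_strat == s]
      p <- if (s == "all") pred_ev else pred_ev[pred_strat == s]
      m <- match_events(r, p, tolerance)
      met <- suppressWarnings(prf1(m))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, onset_type = otype, n_ref = m$n_ref, n_pred = m$n_pred,
        tp = m$tp, fp = m$fp, fn = m$fn,
        precision = met[["precision"]], recall = met[["recall"]],
        f1 = met[["f1"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample size for comparing two proportions
#'
#' Two-sample normal-approximation sample size per group for detecting a
#' change from `p0` to `p1` at two-sided level `alpha` with the given power.
#' The default unpooled variance expression is
#' `ceil((z_{1-alpha/2} + z_{power})^2 (p0(1-p0) + p1(1-p1)) / (p1-p0)^2)`;
#' the pooled (Fleiss) variant is available via `variant = "pooled"`.
#'
#' @param p0,p1 Proportions in (0, 1), `p0 != p1`.
#' @param power Desired power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param variant `"unpooled"` (default) or `"pooled"`.
#' @return Integer sample size (per group).
#' @examples
#' required_sample_size(0.70, 0.80, 0.80, 0.05) # 291
#' @export
required_sample_size <- function(p0, p1, power = 0.80, alpha = 0.05,
                                 variant = c("unpooled", "pooled")) {
  variant <- match.arg(variant)
  if (any(c(p0, p1, power, alpha) <= 0) || any(c(p0, p1, power, alpha) >= 1))
    stop("p0, p1, power and alpha must lie strictly in (0, 1)", call. = FALSE)
  if (p0 == p1) stop("p0 and p1 must differ", call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  d2 <- (p1 - p0)^2
  n <- if (variant == "unpooled") {
    (za + zb)^2 * (p0 * (1 - p0) + p1 * (1 - p1)) / d2
  } else {
    pbar <- (p0 + p1) / 2
    (za * sqrt(2 * pbar * (1 - pbar)) +
       zb * sqrt(p0 * (1 - p0) + p1 * (1 - p1)))^2 / d2
  }
  as.integer(ceiling(n - 1e-9))
}
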