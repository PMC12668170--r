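# Per-breath feature tables and rule-based asynchrony classification.
# A breath is the interval between consecutive inspiratory onsets (the
# cycling convention of the reference standard); breaths lacking an
# expiratory onset or a successor cannot yield Te/TVe and are dropped with
# a recorded count.

#' Per-breath timing and volume features
#'
#' Builds one row per breath from a record's flow channel and a set of
#' onsets: inspiratory time `ti` and expiratory time `te` from onset
#' indices, inhaled volume `tvi` as the trapezoidal integral of positive
#' flow over the inspiratory phase, exhaled volume `tve` as the integral of
#' negative-flow magnitude over the expiratory phase (flow in L/min
#' converted to mL/s), and their ratio `tve/tvi`.
#'
#' @param record A [vent_record()] (the flow channel is integrated).
#' @param annotation Onsets to build breaths from; defaults to the record's
#'   own annotation. If an inspiratory interval contains several expiratory
#'   onsets (unconstrained rule output), the first is used.
#' @return A data frame with columns `breath`, `insp_onset`, `exp_onset`,
#'   `next_insp_onset`, `ti`, `te`, `tvi`, `tve`, `ratio` and (when the
#'   annotation carries them) `btype`. The number of dropped breaths is
#'   attached as attribute `"n_dropped"`.
#' @export
breath_table <- function(record, annotation = record$annotation) {
  stopifnot(inherits(record, "vent_record"))
  if (is.null(annotation)) stop("no annotation supplied", call. = FALSE)
  if (is.null(record$flow)) stop("record has no flow channel", call. = FALSE)
  insp <- sort(as.integer(annotation$insp_onsets))
  expo <- sort(as.integer(annotation$exp_onsets))
  rate <- record$sample_rate
  flow <- record$flow
  nb <- length(insp)
  rows <- vector("list", nb)
  dropped <- 0L
  for (k in seq_len(nb)) {
    nxt <- if (k < nb) insp[k + 1L] else NA_integer_
    e_in <- expo[expo > insp[k] & (is.na(nxt) | expo < nxt)]
    if (is.na(nxt) || !length(e_in)) { dropped <- dropped + 1L; next }
    e <- e_in[1L]
    tvi <- trapz_volume(flow[insp[k]:e], rate, positive = TRUE)
    tve <- trapz_volume(flow[e:nxt], rate, positive = FALSE)
    rows[[k]] <- data.frame(
      breath = k, insp_onset = insp[k], exp_onset = e, next_insp_onset = nxt,
      ti = (e - insp[k]) / rate, te = (nxt - e) / rate,
      tvi = tvi, tve = tve,
      ratio = if (tvi > 0) tve / tvi else NA_real_)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(breath = integer(0), insp_onset = integer(0),
                      exp_onset = integer(0), next_insp_onset = integer(0),
                      ti = numeric(0), te = numeric(0), tvi = numeric(0),
                      tve = numeric(0), ratio = numeric(0))
  if (!is.null(annotation$breath_types) && nrow(out))
    out$btype <- annotation$breath_types[out$breath]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Double-trigger classification, timing definition
#'
#' Flags a breath as double-triggered when its expiratory time is less than
#' half the mean inspiratory time (strict inequality). The mean is computed
#' over the supplied table (pooled over the evaluation cohort); pass
#' `mean_ti` to scope it differently (e.g. per patient).
#'
#' @param rows A [breath_table()] data frame with at least one row.
#' @param mean_ti Optional externally supplied mean inspiratory time (s).
#' @return Logical vector, one flag per row.
#' @export
classify_dt_def1 <- function(rows, mean_ti = NULL) {
  if (!nrow(rows)) stop("empty breath table", call. = FALSE)
  if (is.null(mean_ti)) mean_ti <- mean(rows$ti)
  rows$te < 0.5 * mean_ti
}

#' Double-trigger classification, volume definition
#'
#' Flags a breath as double-triggered when its expiratory time is at most
#' 0.3 s and either TVe/TVi < 0.25, or TVe/TVi < 0.50 with an exhaled
#' volume below 100 mL. Rows with non-positive inhaled volume are excluded
#' (`NA`) with a warning.
#'
#' @param rows A [breath_table()] data frame.
#' @return Logical vector per row (`NA` for excluded rows).
#' @export
classify_dt_def2 <- function(rows) {
  bad <- !(rows$tvi > 0)
  if (any(bad))
    warning(sum(bad), " breath(s) with non-positive TVi excluded", call. = FALSE)
  flag <- rows$te <= 0.3 &
    (rows$ratio < 0.25 | (rows$ratio < 0.50 & rows$tve < 100))
  flag[bad] <- NA
  flag
}

#' Stacked-breath classification
#'
#' Flags a breath as stacked when its expiratory time exceeds 0.3 s
#' (strict) with TVe/TVi < 0.9: a non-trivial expiratory phase that fails
#' to exhale the delivered volume.
#'
#' @param rows A [breath_table()] data frame.
#' @return Logical vector per row (`NA` for rows with non-positive TVi).
#' @export
classify_stacked <- function(rows) {
  bad <- !(rows$tvi > 0)
  if (any(bad))
    warning(sum(bad), " breath(s) with non-positive TVi excluded", call. = FALSE)
  flag <- rows$te > 0.3 & rows$ratio < 0.9
  flag[bad] <- NA
  flag
}

#' Asynchrony frequency report
#'
#' Applies the three printed definitions to a breath table and reports
#' counts and frequencies (asynchronous breaths / total breaths).
#'
#' @param rows A [breath_table()] data frame.
#' @param source Name of the segmentation method the onsets came from.
#' @return An object of class `pva_report`.
#' @export
pva_report <- function(rows, source = "reference") {
  n <- nrow(rows)
  if (!n) stop("empty breath table", call. = FALSE)
  d1 <- classify_dt_def1(rows)
  d2 <- classify_dt_def2(rows)
  st <- classify_stacked(rows)
  cnt <- function(x) sum(x, na.rm = TRUE)
  structure(list(n_breaths = n,
                 dt_def1 = cnt(d1), dt_def2 = cnt(d2), stacked = cnt(st),
                 freq_dt_def1 = cnt(d1) / n, freq_dt_def2 = cnt(d2) / n,
                 freq_stacked = cnt(st) / n,
                 n_excluded = sum(is.na(d2)),
                 n_dropped = attr(rows, "n_dropped") %||% 0L,
                 source = source),
            class = "pva_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pva_report <- function(x, ...) {
  cat(sprintf("<pva_report> %s: %d breaths\n", x$source, x$n_breaths))
  cat(sprintf("  double trigger (timing def):  %d (%.1f%%)\n", x$dt_def1, 100 * x$freq_dt_def1))
  cat(sprintf("  double trigger (volume def):  %d (%.1f%%)\n", x$dt_def2, 100 * x$freq_dt_def2))
  cat(sprintf("  stacked:                      %d (%.1f%%)\n", x$stacked, 100 * x$freq_stacked))
  invisible(x)
}

#' Compare asynchrony frequencies between two segmentation sources
#'
#' For each asynchrony category, forms the 2x2 contingency table of flagged
#' vs non-flagged breaths by source and applies Pearson's chi-squared test
#' without continuity correction (1 df). A zero-margin table yields
#' statistic 0 and p = 1 with a warning.
#'
#' @param report_a,report_b [pva_report()] objects over comparable breath
#'   populations.
#' @return Data frame with one row per category: counts, totals, the
#'   chi-squared statistic and two-sided p-value.
#' @export
compare_frequencies <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "pva_report"), inherits(report_b, "pva_report"))
  cats <- c("dt_def1", "dt_def2", "stacked")
  rows <- lapply(cats, function(cat) {
    a <- report_a[[cat]]; b <- report_b[[cat]]
    na <- report_a$n_breaths; nb <- report_b$n_breaths
    tab <- matrix(c(a, na - a, b, nb - b), nrow = 2, byrow = TRUE)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
      warning("zero margin in contingency table for ", cat, call. = FALSE)
      stat <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value
      if (is.nan(stat)) { stat <- 0; p <- 1 }
    }
    data.frame(category = cat, count_a = a, n_a = na, count_b = b, n_b = nb,
               statistic = stat, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch two-sided t-test helper for continuous breath features
#'
#' @param x,y Numeric vectors.
#' @return Data frame with the t statistic, degrees of freedom and p-value.
#' @export
compare_means <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
}
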