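#' Onset annotation for a ventilator waveform record
#'
#' Holds the ground-truth (or predicted) inspiratory and expiratory onset
#' sample indices for one record, together with a per-breath type label.
#' Indices are 1-based sample positions into the parent record.
#'
#' @param insp_onsets Integer vector of inspiratory onset sample indices,
#'   strictly increasing.
#' @param exp_onsets Integer vector of expiratory onset sample indices,
#'   strictly increasing. Each must fall strictly after the inspiratory onset
#'   of its breath, and at most one may lie between consecutive inspiratory
#'   onsets. A single expiratory onset before the first inspiratory onset is
#'   allowed (a partial breath at the start of the record).
#' @param breath_types Optional character vector aligned to `insp_onsets`,
#'   one of `"normal"`, `"pva"`, `"double_trigger"`, `"stacked"`,
#'   `"artifact"`. The finer double-trigger / stacked labels are folded into
#'   the `pva` stratum by [stratified_eval()].
#' @param n_samples Optional record length for bounds checking.
#'
#' @return An object of class `onset_annotation`.
#' @export
onset_annotation <- function(insp_onsets, exp_onsets = integer(0),
                             breath_types = NULL, n_samples = NULL) {
  insp_onsets <- as.integer(insp_onsets)
  exp_onsets <- as.integer(exp_onsets)
  if (is.unsorted(insp_onsets, strictly = TRUE))
    stop("insp_onsets must be strictly increasing", call. = FALSE)
  if (is.unsorted(exp_onsets, strictly = TRUE))
    stop("exp_onsets must be strictly increasing", call. = FALSE)
  if (length(insp_onsets) && any(insp_onsets < 1L))
    stop("onset indices must be >= 1", call. = FALSE)
  if (!is.null(n_samples)) {
    if (length(insp_onsets) && max(insp_onsets) > n_samples)
      stop("inspiratory onset beyond record bounds", call. = FALSE)
    if (length(exp_onsets) && max(exp_onsets) > n_samples)
      stop("expiratory onset beyond record bounds", call. = FALSE)
  }
  if (length(exp_onsets)) {
    if (any(exp_onsets %in% insp_onsets))
      stop("each expiratory onset must be strictly after the inspiratory onset of its breath",
           call. = FALSE)
    # at most one expiratory onset per inspiratory interval; interval 0 is
    # the open segment before the first inspiratory onset (a partial
    # leading breath), where a single expiratory onset is allowed
    interval <- findInterval(exp_onsets, insp_onsets)
    if (anyDuplicated(interval))
      stop("more than one expiratory onset between consecutive inspiratory onsets",
           call. = FALSE)
  }
  if (!is.null(breath_types)) {
    breath_types <- as.character(breath_types)
    if (length(breath_types) != length(insp_onsets))
      stop("breath_types must align with insp_onsets", call. = FALSE)
    ok <- breath_types %in% c("normal", "pva", "double_trigger", "stacked", "artifact")
    if (!all(ok))
      stop("unknown breath type: ", paste(unique(breath_types[!ok]), collapse = ", "),
           call. = FALSE)
  }
  structure(list(insp_onsets = insp_onsets, exp_onsets = exp_onsets,
                 breath_types = breath_types),
            class = "onset_annotation")
}

#' @export
print.onset_annotation <- function(x, ...) {
  cat(sprintf("<onset_annotation> %d inspiratory, %d expiratory onsets\n",
              length(x$insp_onsets), length(x$exp_onsets)))
  if (!is.null(x$breath_types))
    print(table(x$breath_types))
  invisible(x)
}

#' Two-channel ventilator waveform record
#'
#' A patient's airway pressure (cm H2O) and flow (L/min) series sampled
#' uniformly (default 50 Hz), with an optional [onset_annotation()].
#'
#' @param patient_id Character identifier.
#' @param pressure,flow Numeric vectors of equal length.
#' @param sample_rate Sampling frequency in Hz (default 50).
#' @param time Optional time stamps in seconds; when omitted, computed as
#'   `(seq_along(flow) - 1) / sample_rate`. Must step uniformly by
#'   `1/sample_rate` within 1e-9 s.
#' @param annotation Optional [onset_annotation()].
#'
#' @return An object of class `vent_record`.
#' @export
vent_record <- function(patient_id, pressure, flow, sample_rate = 50,
                        time = NULL, annotation = NULL) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar", call. = FALSE)
  n <- length(flow)
  if (length(pressure) != n)
    stop("pressure and flow must have identical length", call. = FALSE)
  if (n < 1L) stop("record must contain at least one sample", call. = FALSE)
  if (is.null(time)) {
    time <- (seq_len(n) - 1) / sample_rate
  } else {
    if (length(time) != n)
      stop("time must have the same length as pressure and flow", call. = FALSE)
    if (n > 1L) {
      dt <- diff(time)
      bad <- which(abs(dt - 1 / sample_rate) > 1e-9)
      if (length(bad))
        stop(sprintf("non-uniform time step at index %d (step %.6g s, expected %.6g s)",
                     bad[1] + 1L, dt[bad[1]], 1 / sample_rate), call. = FALSE)
    }
  }
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "onset_annotation"))
    # re-validate bounds against this record
    annotation <- onset_annotation(annotation$insp_onsets, annotation$exp_onsets,
                                   annotation$breath_types, n_samples = n)
  }
  structure(list(patient_id = as.character(patient_id),
                 sample_rate = sample_rate,
                 time = as.numeric(time),
                 pressure = as.numeric(pressure),
                 flow = as.numeric(flow),
                 annotation = annotation),
            class = "vent_record")
}

#' @export
print.vent_record <- function(x, ...) {
  cat(sprintf("<vent_record> patient %s: %d samples (%.1f s at %g Hz)%s\n",
              x$patient_id, length(x$flow), length(x$flow) / x$sample_rate,
              x$sample_rate,
              if (is.null(x$annotation)) "" else ", annotated"))
  invisible(x)
}

#' @export
length.vent_record <- function(x) length(x$flow)

#' Read a ventilator waveform record from columnar text
#'
#' Expects a comma-separated file with header columns `time`, `pressure`,
#' `flow` and optionally `insp_onset`, `exp_onset` (0/1 flags per sample) and
#' `breath_type` (non-empty at inspiratory onset samples).
#'
#' @param path File path.
#' @param sample_rate Sampling rate in Hz; when `NULL`, inferred from the
#'   median time step and then validated against every step.
#' @param patient_id Identifier for the record; defaults to the file name
#'   without extension.
#'
#' @return A [vent_record()].
#' @export
read_record <- function(path, sample_rate = NULL, patient_id = NULL) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  need <- c("time", "pressure", "flow")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(sample_rate)) {
    if (nrow(dt) < 2L)
      stop("cannot infer sample_rate from a single row; pass sample_rate",
           call. = FALSE)
    step <- stats::median(diff(dt$time))
    if (step <= 0)
      stop("non-positive time step; cannot infer sample_rate", call. = FALSE)
    sample_rate <- 1 / step
    # snap to an integer rate when the data are within float noise of one
    if (abs(sample_rate - round(sample_rate)) < 1e-6)
      sample_rate <- round(sample_rate)
  }
  ann <- NULL
  if (all(c("insp_onset", "exp_onset") %in% names(dt))) {
    insp <- which(dt$insp_onset > 0)
    expo <- which(dt$exp_onset > 0)
    types <- NULL
    if ("breath_type" %in% names(dt)) {
      bt <- as.character(dt$breath_type[insp])
      if (length(bt) && any(nzchar(bt))) types <- bt
    }
    if (length(insp) || length(expo))
      ann <- onset_annotation(insp, expo, types, n_samples = nrow(dt))
  }
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  vent_record(patient_id, dt$pressure, dt$flow, sample_rate,
              time = dt$time, annotation = ann)
}

#' Write a ventilator waveform record to CSV
#'
#' Inverse of [read_record()]: numeric columns round-trip at full precision.
#'
#' @param record A [vent_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "vent_record"))
  n <- length(record$flow)
  df <- data.frame(time = record$time, pressure = record$pressure,
                   flow = record$flow)
  if (!is.null(record$annotation)) {
    ann <- record$annotation
    insp <- integer(n); insp[ann$insp_onsets] <- 1L
    expo <- integer(n); expo[ann$exp_onsets] <- 1L
    df$insp_onset <- insp
    df$exp_onset <- expo
    bt <- character(n)
    if (!is.null(ann$breath_types)) bt[ann$insp_onsets] <- ann$breath_types
    df$breath_type <- bt
  }
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' Convert a duration to a sample count
#'
#' The model's window geometry is stated in seconds (7.04 s input, 3.52 s
#' output at 50 Hz); this converts a duration to the corresponding integral
#' number of samples and refuses non-integral products.
#'
#' @param duration Duration in seconds, > 0.
#' @param sample_rate Sampling rate in Hz, > 0.
#' @return Integer sample count `round(duration * sample_rate)`.
#' @examples
#' window_samples(7.04, 50) # 352
#' window_samples(3.52, 50) # 176
#' @export
window_samples <- function(duration, sample_rate) {
  if (duration <= 0 || sample_rate <= 0)
    stop("duration and sample_rate must be positive", call. = FALSE)
  prod <- duration * sample_rate
  if (abs(prod - round(prod)) > 1e-9)
    stop(sprintf("duration %g s is not an integral number of samples at %g Hz",
                 duration, sample_rate), call. = FALSE)
  as.integer(round(prod))
}

# Mirror (reflection) index into 1..n without repeating the edge sample;
# valid for arbitrary out-of-range j via the period-2(n-1) fold.
mirror_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  m <- (j - 1L) %% (2L * n - 2L)
  ifelse(m < n, m + 1L, 2L * n - 1L - m)
}

#' Per-window channel normalization
#'
#' Each channel of an input window is z-scored within the window: subtract
#' the within-window mean and divide by the within-window population
#' (divide-by-n) standard deviation. A constant channel maps to all zeros.
#'
#' @param window Numeric matrix, timesteps x channels.
#' @return Matrix of the same shape with per-channel mean 0 and sd 1
#'   (population convention), or zeros for constant channels.
#' @export
normalize_window <- function(window) {
  window <- as.matrix(window)
  out <- window
  for (c in seq_len(ncol(window))) {
    x <- window[, c]
    mu <- mean(x)
    sdp <- sqrt(mean((x - mu)^2))
    out[, c] <- if (sdp < 1e-12) 0 else (x - mu) / sdp
  }
  out
}

#' Slice a record into model windows
#'
#' Tiles the record with output spans of `output_len` samples at the given
#' step (non-overlapping at the default step), each paired with an input
#' window extending `(input_len - output_len)/2` samples beyond the output
#' span on each side. Record edges are reflection-padded on the raw signals
#' before per-window normalization. If the record is annotated, binary
#' targets carry a 1 exactly at onset samples inside each output span
#' (channel 1 = inspiratory, channel 2 = expiratory); otherwise targets are
#' omitted and the batch is inference-only.
#'
#' @param record A [vent_record()].
#' @param input_len Input window length in samples (default 352; must be even).
#' @param output_len Output span length (default 176; must be <= input_len
#'   with an even difference).
#' @param step Step between consecutive output spans (default `output_len`).
#' @return An object of class `window_batch` with elements `inputs`
#'   (N x input_len x 2 normalized array), `targets` (N x output_len x 2
#'   binary array or NULL), `window_starts` (record coordinate of each input
#'   window's first sample; may be <= 0 in the padded region), `out_starts`,
#'   `record_ids`, and the geometry fields.
#' @export
make_windows <- function(record, input_len = 352L, output_len = 176L,
                         step = output_len) {
  stopifnot(inherits(record, "vent_record"))
  input_len <- as.integer(input_len); output_len <- as.integer(output_len)
  step <- as.integer(step)
  if (input_len %% 2L != 0L) stop("input_len must be even", call. = FALSE)
  if (output_len > input_len) stop("output_len must be <= input_len", call. = FALSE)
  if ((input_len - output_len) %% 2L != 0L)
    stop("input_len - output_len must be even", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  n <- length(record$flow)
  if (n < output_len)
    stop(sprintf("record of %d samples is shorter than output_len %d", n, output_len),
         call. = FALSE)
  pad <- (input_len - output_len) %/% 2L
  K <- if (n == output_len) 1L else as.integer(ceiling((n - output_len) / step)) + 1L
  out_starts <- 1L + (seq_len(K) - 1L) * step
  win_starts <- out_starts - pad

  inputs <- array(0, dim = c(K, input_len, 2L))
  has_ann <- !is.null(record$annotation)
  targets <- if (has_ann) array(0, dim = c(K, output_len, 2L)) else NULL
  raw <- cbind(record$pressure, record$flow)
  for (k in seq_len(K)) {
    idx <- mirror_index(win_starts[k] + 0:(input_len - 1L), n)
    inputs[k, , ] <- normalize_window(raw[idx, , drop = FALSE])
    if (has_ann) {
      o0 <- out_starts[k]
      for (ch in 1:2) {
        ons <- if (ch == 1L) record$annotation$insp_onsets else record$annotation$exp_onsets
        inside <- ons[ons >= o0 & ons < o0 + output_len]
        if (length(inside)) targets[k, inside - o0 + 1L, ch] <- 1
      }
    }
  }
  structure(list(inputs = inputs, targets = targets,
                 window_starts = win_starts, out_starts = out_starts,
                 record_ids = rep(record$patient_id, K),
                 input_len = input_len, output_len = output_len, step = step,
                 sample_rate = record$sample_rate, n_samples = n),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  cat(sprintf("<window_batch> %d windows of %d samples (%d-sample output spans)%s\n",
              dim(x$inputs)[1], x$input_len, x$output_len,
              if (is.null(x$targets)) ", inference-only" else ""))
  invisible(x)
}

# Concatenate window batches (e.g. across records) into one batch.
# Geometry must agree; targets kept only if present in all parts.
bind_window_batches <- function(batches) {
  stopifnot(length(batches) >= 1L)
  g <- batches[[1L]]
  for (b in batches) {
    stopifnot(inherits(b, "window_batch"),
              b$input_len == g$input_len, b$output_len == g$output_len)
  }
  all_t <- all(vapply(batches, function(b) !is.null(b$targets), logical(1)))
  abind1 <- function(field) {
    arrs <- lapply(batches, `[[`, field)
    out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], numeric(1))),
                            dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
    at <- 0L
    for (a in arrs) {
      out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
  structure(list(inputs = abind1("inputs"),
                 targets = if (all_t) abind1("targets") else NULL,
                 window_starts = unlist(lapply(batches, `[[`, "window_starts")),
                 out_starts = unlist(lapply(batches, `[[`, "out_starts")),
                 record_ids = unlist(lapply(batches, `[[`, "record_ids")),
                 input_len = g$input_len, output_len = g$output_len,
                 step = g$step, sample_rate = g$sample_rate,
                 n_samples = NA_integer_),
            class = "window_batch")
}
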