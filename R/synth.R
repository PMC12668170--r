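# Synthetic two-channel ventilator waveforms with planted ground truth.
# Calibrated to the cohort statistics of adult volume-targeted ventilation:
# Ti ~ 0.8-0.9 s, Te ~ 1.1-2.8 s, peak flow ~ 50-80 L/min (decelerating) or
# 25-36 L/min (square), peak pressure ~ 21-34 cm H2O, tidal volume ~ 300-500 mL.

#' Specification of one synthetic breath
#'
#' @param ti Inspiratory duration (s), > 0.
#' @param te Expiratory duration (s), > 0.
#' @param peak_flow Peak inspiratory flow (L/min), > 0.
#' @param peep Positive end-expiratory pressure (cm H2O).
#' @param peak_pressure Peak airway pressure (cm H2O).
#' @param insp_shape `"square"` (constant flow) or `"decelerating"`
#'   (linear ramp from peak to zero).
#' @param exhale_fraction Fraction of the inhaled volume exhaled before the
#'   next trigger, in (0, 1]. Values well below 1 plant incomplete exhalation
#'   (breath stacking); combined with a very short `te` they plant the first
#'   insufflation of a double trigger.
#' @param btype Breath type label: `"normal"`, `"double_trigger"`,
#'   `"stacked"` or `"artifact"`.
#' @return An object of class `breath_spec`.
#' @export
breath_spec <- function(ti, te, peak_flow, peep = 5, peak_pressure = 25,
                        insp_shape = c("decelerating", "square"),
                        exhale_fraction = 1, btype = "normal") {
  insp_shape <- match.arg(insp_shape)
  if (ti <= 0 || te <= 0) stop("ti and te must be positive", call. = FALSE)
  if (peak_flow <= 0) stop("peak_flow must be positive", call. = FALSE)
  if (exhale_fraction <= 0 || exhale_fraction > 1)
    stop("exhale_fraction must be in (0, 1]", call. = FALSE)
  structure(list(ti = ti, te = te, peak_flow = peak_flow, peep = peep,
                 peak_pressure = peak_pressure, insp_shape = insp_shape,
                 exhale_fraction = exhale_fraction, btype = btype),
            class = "breath_spec")
}

# Trapezoidal volume (mL) of the positive part of a flow trace (L/min)
# sampled at `rate` Hz, over the inclusive node range given.
trapz_volume <- function(flow, rate, positive = TRUE) {
  v <- if (positive) pmax(flow, 0) else pmax(-flow, 0)
  if (length(v) < 2L) return(0)
  sum((v[-1] + v[-length(v)]) / 2) / rate * (1000 / 60)
}

#' Generate one synthetic breath
#'
#' Inspiration follows the requested flow shape at the requested peak;
#' expiration is a single exponential decay (time constant `te/3`) scaled so
#' that the exhaled volume equals `exhale_fraction` times the inhaled volume
#' under the same trapezoidal integration convention used by
#' [breath_table()]. Pressure rises from PEEP toward the peak during
#' inspiration and decays back to PEEP during expiration.
#'
#' @param spec A [breath_spec()].
#' @param sample_rate Sampling rate in Hz (default 50).
#' @return A list with `flow` and `pressure` segments (length
#'   `round((ti + te) * sample_rate)`), and 1-based onset offsets
#'   `insp_onset` (always 1) and `exp_onset` (`round(ti * sample_rate) + 1`).
#' @export
synth_breath <- function(spec, sample_rate = 50) {
  stopifnot(inherits(spec, "breath_spec"))
  n_i <- as.integer(round(spec$ti * sample_rate))
  n_e <- as.integer(round(spec$te * sample_rate))
  if (n_i < 2L || n_e < 2L)
    stop("ti and te must each span at least 2 samples", call. = FALSE)
  dt <- 1 / sample_rate

  insp_flow <- switch(spec$insp_shape,
    square = rep(spec$peak_flow, n_i),
    decelerating = spec$peak_flow * (1 - (0:(n_i - 1)) / n_i))

  # inhaled volume with the node at the expiratory onset clipped to zero
  # (flow is negative there), matching breath_table's convention
  tvi <- trapz_volume(c(insp_flow, 0), sample_rate)

  u <- exp(-(0:(n_e - 1)) * dt / (spec$te / 3))
  # unscaled exhaled volume with the node at the next inspiratory onset
  # clipped to zero (flow positive there)
  vol_u <- trapz_volume(c(-u, 0), sample_rate, positive = FALSE)
  amp <- spec$exhale_fraction * tvi / vol_u
  exp_flow <- -amp * u

  t_i <- (0:(n_i - 1)) * dt
  t_e <- (0:(n_e - 1)) * dt
  insp_p <- spec$peep + (spec$peak_pressure - spec$peep) * (1 - exp(-3 * t_i / spec$ti))
  p_end <- insp_p[n_i]
  exp_p <- spec$peep + (p_end - spec$peep) * exp(-t_e / (spec$te / 5))

  list(flow = c(insp_flow, exp_flow), pressure = c(insp_p, exp_p),
       insp_onset = 1L, exp_onset = n_i + 1L, tvi = tvi,
       tve = spec$exhale_fraction * tvi)
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate the study conditions of an adult ICU cohort enriched for
#' asynchrony: 33 patients of ~294 breaths each, ~30% of breaths planted as
#' asynchronous (split evenly between double-trigger insufflations and
#' stacked breaths by default) and ~5% as artifact-laden, with additive
#' Gaussian sensor noise and slow baseline wander.
#'
#' @param n_patients Number of synthetic patients.
#' @param breaths_per_patient Breaths per patient.
#' @param asynchrony_fraction Per-breath probability of planting an
#'   asynchronous breath (double trigger or stacked), in \[0, 1\].
#' @param artifact_fraction Per-breath probability of an artifact-laden
#'   breath, in \[0, 1\].
#' @param dt_share Fraction of asynchronous breaths that are double-trigger
#'   insufflations (the rest are stacked).
#' @param noise_sd_flow Additive Gaussian noise sd on flow (L/min).
#' @param noise_sd_pressure Additive Gaussian noise sd on pressure (cm H2O).
#' @param baseline_wander_amplitude Length-2 named vector
#'   `c(flow = , pressure = )`: amplitude of slow (0.05-0.15 Hz) sinusoidal
#'   baseline wander per channel.
#' @param seed Integer seed; the whole cohort is reproducible from it, with
#'   per-patient substreams derived by fixed offsets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 33L, breaths_per_patient = 294L,
                       asynchrony_fraction = 0.30, artifact_fraction = 0.05,
                       dt_share = 0.5,
                       noise_sd_flow = 1.0, noise_sd_pressure = 0.5,
                       baseline_wander_amplitude = c(flow = 0.3, pressure = 0.3),
                       seed = 1L) {
  stopifnot(n_patients >= 1L, breaths_per_patient >= 1L,
            asynchrony_fraction >= 0, asynchrony_fraction <= 1,
            artifact_fraction >= 0, artifact_fraction <= 1,
            dt_share >= 0, dt_share <= 1,
            noise_sd_flow >= 0, noise_sd_pressure >= 0)
  bw <- baseline_wander_amplitude
  if (is.null(names(bw))) names(bw) <- c("flow", "pressure")
  structure(list(n_patients = as.integer(n_patients),
                 breaths_per_patient = as.integer(breaths_per_patient),
                 asynchrony_fraction = asynchrony_fraction,
                 artifact_fraction = artifact_fraction,
                 dt_share = dt_share,
                 noise_sd_flow = noise_sd_flow,
                 noise_sd_pressure = noise_sd_pressure,
                 baseline_wander_amplitude = bw,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Draw the planted parameters of one breath of the given type.
draw_breath_spec <- function(btype) {
  shape <- if (stats::runif(1) < 0.2) "square" else "decelerating"
  peak <- if (shape == "square") stats::runif(1, 25, 36) else stats::runif(1, 45, 70)
  ti <- stats::runif(1, 0.8, 0.9)
  # asynchrony geometry keeps te and TVe/TVi at least 0.05 from every
  # classification boundary (te 0.3 s; ratios 0.25, 0.5, 0.9)
  par <- switch(btype,
    normal = ,
    artifact = list(te = stats::runif(1, 1.1, 2.8), ef = stats::runif(1, 0.96, 1.0)),
    double_trigger = list(te = stats::runif(1, 0.10, 0.25), ef = stats::runif(1, 0.05, 0.20)),
    stacked = list(te = stats::runif(1, 0.5, 1.2), ef = stats::runif(1, 0.5, 0.85)))
  breath_spec(ti = ti, te = par$te, peak_flow = peak,
              peep = stats::runif(1, 5, 8),
              peak_pressure = stats::runif(1, 21, 34),
              insp_shape = shape, exhale_fraction = par$ef, btype = btype)
}

# Cough-like artifact: a damped 10 Hz oscillatory burst.
artifact_burst <- function(n, rate) {
  t <- (0:(n - 1)) / rate
  20 * exp(-t / 0.08) * sin(2 * pi * 10 * t)
}

synth_patient <- function(config, patient_id, seed) {
  with_seed(seed, {
    rate <- 50
    nb <- config$breaths_per_patient
    u <- stats::runif(nb)
    p_dt <- config$asynchrony_fraction * config$dt_share
    p_st <- config$asynchrony_fraction
    p_art <- config$asynchrony_fraction + config$artifact_fraction
    btypes <- ifelse(u < p_dt, "double_trigger",
              ifelse(u < p_st, "stacked",
              ifelse(u < p_art, "artifact", "normal")))

    # lead-in: record starts mid-exhalation so the first inspiratory onset
    # is a genuine negative-to-positive flow crossing
    lead_n <- as.integer(1.0 * rate)
    t_lead <- (0:(lead_n - 1)) / rate
    flow <- list(-6 * exp(-t_lead / 0.3))
    peep0 <- 6
    pressure <- list(rep(peep0, lead_n))

    insp <- integer(nb); expo <- integer(nb)
    planted <- vector("list", nb)
    at <- lead_n
    for (b in seq_len(nb)) {
      sp <- draw_breath_spec(btypes[b])
      br <- synth_breath(sp, rate)
      insp[b] <- at + br$insp_onset
      expo[b] <- at + br$exp_onset
      flow[[b + 1L]] <- br$flow
      pressure[[b + 1L]] <- br$pressure
      planted[[b]] <- data.frame(breath = b, btype = btypes[b], ti = sp$ti,
                                 te = sp$te, exhale_fraction = sp$exhale_fraction,
                                 peak_flow = sp$peak_flow, tvi = br$tvi,
                                 insp_onset = insp[b], exp_onset = expo[b])
      at <- at + length(br$flow)
    }
    flow <- unlist(flow)
    pressure <- unlist(pressure)
    n <- length(flow)

    # noise and wander are added only after the ground truth is recorded
    bw <- config$baseline_wander_amplitude
    tt <- (0:(n - 1)) / rate
    if (bw[["flow"]] > 0)
      flow <- flow + bw[["flow"]] *
        sin(2 * pi * stats::runif(1, 0.05, 0.15) * tt + stats::runif(1, 0, 2 * pi))
    if (bw[["pressure"]] > 0)
      pressure <- pressure + bw[["pressure"]] *
        sin(2 * pi * stats::runif(1, 0.05, 0.15) * tt + stats::runif(1, 0, 2 * pi))
    if (config$noise_sd_flow > 0)
      flow <- flow + stats::rnorm(n, 0, config$noise_sd_flow)
    if (config$noise_sd_pressure > 0)
      pressure <- pressure + stats::rnorm(n, 0, config$noise_sd_pressure)
    for (b in which(btypes == "artifact")) {
      len <- as.integer(0.3 * rate)
      lo <- insp[b] + sample.int(max(1L, expo[b] - insp[b]), 1L) - 1L
      idx <- lo:min(n, lo + len - 1L)
      flow[idx] <- flow[idx] + artifact_burst(length(idx), rate)
      pressure[idx] <- pressure[idx] + 0.3 * artifact_burst(length(idx), rate)
    }

    ann <- onset_annotation(insp, expo, btypes, n_samples = n)
    rec <- vent_record(patient_id, pressure, flow, rate, annotation = ann)
    attr(rec, "planted") <- do.call(rbind, planted)
    rec
  })
}

#' Simulate a labeled synthetic ventilator cohort
#'
#' Generates one [vent_record()] per synthetic patient by concatenating
#' breaths drawn under the configuration, planting double-trigger
#' insufflations (te 0.10-0.25 s, TVe/TVi 0.05-0.20 -- the following breath
#' starts immediately at the end of the truncated expiration), stacked
#' breaths (te 0.5-1.2 s, TVe/TVi 0.5-0.85) and normal breaths (te
#' 1.1-2.8 s, TVe/TVi >= 0.96). Sensor noise, baseline wander and
#' cough-like artifact bursts are added only after the exact onset indices
#' are recorded, so annotations are exact. Each record carries a `"planted"`
#' attribute: a data frame of the drawn per-breath parameters.
#'
#' @param config A [sim_config()].
#' @return A list of annotated [vent_record()] objects, one per patient.
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lapply(seq_len(config$n_patients), function(i) {
    synth_patient(config, sprintf("synth%03d", i),
                  seed = config$seed + 10007L * i)
  })
}
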