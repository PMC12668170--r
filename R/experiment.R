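# End-to-end experiment driver: simulate a cohort, split by patient, train
# the U-Net, segment the held-out test records with the U-Net and both
# heuristics, evaluate exact and tolerance-window metrics (pooled and
# stratified), quantify asynchrony from each segmentation source, and
# compare frequencies against the reference standard.

#' Experiment configuration
#'
#' @param sim A [sim_config()].
#' @param model A [model_config()].
#' @param loss A [loss_config()].
#' @param train A [train_config()].
#' @param split Named fractions `c(train = , val = , test = )` summing to 1;
#'   applied at the patient level so no patient appears in two cohorts.
#' @param tolerance Matching tolerance in seconds (default 0.1).
#' @param seed Master seed for the patient-split shuffle.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(), model = model_config(),
                              loss = loss_config(), train = train_config(),
                              split = c(train = 0.8, val = 0.1, test = 0.1),
                              tolerance = 0.1, seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-9, all(split > 0), tolerance >= 0)
  structure(list(sim = sim, model = model, loss = loss, train = train,
                 split = split, tolerance = tolerance, seed = as.integer(seed)),
            class = "experiment_config")
}

# Deterministic patient-level split; returns a factor over records.
split_patients <- function(n, fractions, seed) {
  with_seed(seed, {
    ord <- sample.int(n)
    n_tr <- max(1L, round(fractions[["train"]] * n))
    n_va <- max(1L, round(fractions[["val"]] * n))
    if (n_tr + n_va >= n) { n_tr <- n - 2L; n_va <- 1L }
    grp <- rep("test", n)
    grp[ord[seq_len(n_tr)]] <- "train"
    grp[ord[n_tr + seq_len(n_va)]] <- "val"
    grp
  })
}

# Pooled metrics for one prediction source on a list of (reference,
# predicted) annotation pairs, at a tolerance in samples.
pooled_metrics <- function(refs, preds, tol_samples) {
  agg <- function(field) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(refs)) {
      m <- match_events(refs[[i]][[field]], preds[[i]][[field]], tol_samples)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    met <- suppressWarnings(prf1(list(tp = tp, fp = fp, fn = fn)))
    data.frame(onset_type = sub("_onsets", "", field), tp = tp, fp = fp,
               fn = fn, precision = met[["precision"]],
               recall = met[["recall"]], f1 = met[["f1"]])
  }
  rbind(agg("insp_onsets"), agg("exp_onsets"))
}

# Breath tables and PVA report pooled over a list of records for one
# segmentation source.
pooled_pva <- function(records, annotations, source) {
  tabs <- mapply(function(rec, ann) breath_table(rec, ann),
                 records, annotations, SIMPLIFY = FALSE)
  dropped <- sum(vapply(tabs, function(t) attr(t, "n_dropped"), numeric(1)))
  tab <- do.call(rbind, tabs)
  attr(tab, "n_dropped") <- dropped
  pva_report(tab, source = source)
}

#' Run the full segmentation experiment
#'
#' Simulates the configured synthetic cohort, splits it by patient, trains
#' the U-Net on the training/validation cohorts, segments the test records
#' with the trained model and both heuristic baselines, and evaluates
#' onset detection (exact and within-tolerance, pooled and stratified by
#' breath type) and asynchrony quantification (the three printed
#' definitions, each source compared against the reference standard by
#' chi-squared). Fully reproducible from the seeds in the configuration.
#'
#' @param config An [experiment_config()].
#' @param out Optional directory; when given, the report is written there
#'   as JSON plus CSV metric tables.
#' @param verbose Print stage progress.
#' @return A list report: `metrics` (data frame across methods, onset
#'   types and tolerances), `stratified` (per breath-type stratum),
#'   `pva` (per-source reports), `pva_comparisons`, `history`, `split`.
#' @export
run_experiment <- function(config = experiment_config(), out = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulate: %d patients x %d breaths", config$sim$n_patients,
      config$sim$breaths_per_patient)
  cohort <- synth_cohort(config$sim)
  grp <- split_patients(length(cohort), config$split, config$seed)
  if (any(table(grp) < 1L)) stop("degenerate patient split", call. = FALSE)

  say("windows: building training batches")
  wins <- lapply(cohort, make_windows, input_len = config$model$input_len,
                 output_len = config$model$output_len)
  train_b <- bind_window_batches(wins[grp == "train"])
  val_b <- bind_window_batches(wins[grp == "val"])
  test_recs <- cohort[grp == "test"]

  say("train: %d windows (val %d)", dim(train_b$inputs)[1], dim(val_b$inputs)[1])
  model <- train_unet(train_b, val_b, config$model, config$loss, config$train,
                      verbose = verbose)
  say("train: stopped at best epoch %d", model$best_epoch)

  say("segment: %d test records", length(test_recs))
  refs <- lapply(test_recs, `[[`, "annotation")
  preds <- list(
    unet = lapply(test_recs, function(r) predict_record(model, r)$events),
    zero_crossing = lapply(test_recs, zero_crossing_segment),
    derivative_backtracking = lapply(test_recs, derivative_backtrack_segment))

  rate <- test_recs[[1]]$sample_rate
  tol_samples <- as.integer(round(config$tolerance * rate))
  say("evaluate: exact and +/-%d-sample tolerance", tol_samples)
  metrics <- do.call(rbind, lapply(names(preds), function(meth) {
    do.call(rbind, lapply(c(0L, tol_samples), function(tol) {
      m <- pooled_metrics(refs, preds[[meth]], tol)
      m$method <- meth
      m$tolerance_samples <- tol
      m
    }))
  }))

  stratified <- do.call(rbind, lapply(names(preds), function(meth) {
    st <- do.call(rbind, lapply(seq_along(test_recs), function(i) {
      s <- stratified_eval(refs[[i]], preds[[meth]][[i]], tol_samples)
      s$record <- test_recs[[i]]$patient_id
      s
    }))
    st$method <- meth
    st
  }))

  say("pva: quantifying asynchrony per source")
  pva <- list(reference = pooled_pva(test_recs, refs, "reference"))
  for (meth in c("unet", "derivative_backtracking"))
    pva[[meth]] <- pooled_pva(test_recs, preds[[meth]], meth)
  pva_comparisons <- do.call(rbind, lapply(
    c("unet", "derivative_backtracking"), function(meth) {
      cmp <- compare_frequencies(pva$reference, pva[[meth]])
      cmp$method <- meth
      cmp
    }))

  report <- list(metrics = metrics, stratified = stratified, pva = pva,
                 pva_comparisons = pva_comparisons, history = model$history,
                 best_epoch = model$best_epoch,
                 split = data.frame(patient = vapply(cohort, `[[`, "", "patient_id"),
                                    cohort = grp),
                 model = model)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
    utils::write.csv(stratified, file.path(out, "stratified.csv"), row.names = FALSE)
    utils::write.csv(pva_comparisons, file.path(out, "pva_comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(metrics = metrics,
           pva = lapply(pva, unclass),
           pva_comparisons = pva_comparisons,
           best_epoch = model$best_epoch),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
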