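# Training (AdamW + early stopping), sliding-window inference, and event
# post-processing for the breath-segmentation U-Net.

# Composite loss, its value and per-head logit gradients, for one batch.
# Under "by_loss" pairing (the default), the focal and dice terms are each
# computed over the concatenation of both heads' outputs and weighted by
# one learned uncertainty each; under "by_head", each head's focal+dice sum
# gets its own uncertainty.
unet_loss <- function(fw, targets, log_sig, lc, want_grads = TRUE) {
  p1 <- fw$p_insp; p2 <- fw$p_exp
  g1 <- targets[, , 1L, drop = FALSE]; g2 <- targets[, , 2L, drop = FALSE]
  s1 <- log_sig[1]; s2 <- log_sig[2]
  if (lc$pairing == "by_loss") {
    pc <- c(p1, p2); gc <- c(g1, g2)
    lf <- focal_loss(pc, gc, lc$alpha, lc$gamma)
    ld <- dice_loss(pc, gc, lc$epsilon)
    total <- 0.5 * exp(-s1) * lf + 0.5 * exp(-s2) * ld + 0.5 * (s1 + s2)
    if (!want_grads) return(list(total = total, focal = lf, dice = ld))
    dp <- 0.5 * exp(-s1) * focal_grad(pc, gc, lc$alpha, lc$gamma) +
      0.5 * exp(-s2) * dice_grad(pc, gc, lc$epsilon)
    n1 <- length(p1)
    dp1 <- array(dp[seq_len(n1)], dim(p1))
    dp2 <- array(dp[n1 + seq_len(length(p2))], dim(p2))
    dsig <- c(0.5 - 0.5 * exp(-s1) * lf, 0.5 - 0.5 * exp(-s2) * ld)
  } else {
    lf1 <- focal_loss(p1, g1, lc$alpha, lc$gamma)
    ld1 <- dice_loss(p1, g1, lc$epsilon)
    lf2 <- focal_loss(p2, g2, lc$alpha, lc$gamma)
    ld2 <- dice_loss(p2, g2, lc$epsilon)
    L1 <- lf1 + ld1; L2 <- lf2 + ld2
    total <- 0.5 * exp(-s1) * L1 + 0.5 * exp(-s2) * L2 + 0.5 * (s1 + s2)
    if (!want_grads) return(list(total = total, focal = lf1 + lf2, dice = ld1 + ld2))
    dp1 <- 0.5 * exp(-s1) * (focal_grad(p1, g1, lc$alpha, lc$gamma) +
                               dice_grad(p1, g1, lc$epsilon))
    dp2 <- 0.5 * exp(-s2) * (focal_grad(p2, g2, lc$alpha, lc$gamma) +
                               dice_grad(p2, g2, lc$epsilon))
    dp1 <- array(dp1, dim(p1)); dp2 <- array(dp2, dim(p2))
    dsig <- c(0.5 - 0.5 * exp(-s1) * L1, 0.5 - 0.5 * exp(-s2) * L2)
  }
  dz1 <- dp1 * fw$p_insp * (1 - fw$p_insp)
  dz2 <- dp2 * fw$p_exp * (1 - fw$p_exp)
  list(total = total, dz_insp = dz1, dz_exp = dz2, dsig = dsig)
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay applies to convolution/dense weight tensors only
# (not biases, layer-norm parameters or the uncertainty parameters).
adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (grepl("\\.(W|W1|W2|Wt|Wp|Wpsi)$", nm))
      upd <- upd + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

slice_batch <- function(batch, idx) {
  list(inputs = batch$inputs[idx, , , drop = FALSE],
       targets = batch$targets[idx, , , drop = FALSE])
}

# Forward a (possibly large) set of windows in chunks, returning stacked
# probability arrays.
forward_chunked <- function(params, cfg, inputs, chunk = 64L) {
  n <- dim(inputs)[1]
  p1 <- array(0, c(n, cfg$output_len, 1L))
  p2 <- array(0, c(n, cfg$output_len, 1L))
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + chunk - 1L)
    fw <- unet_forward(params, cfg, inputs[idx, , , drop = FALSE],
                       training = FALSE)
    p1[idx, , ] <- fw$p_insp
    p2[idx, , ] <- fw$p_exp
    at <- at + chunk
  }
  list(p_insp = p1, p_exp = p2)
}

#' Train the breath-segmentation U-Net
#'
#' He-initializes the network and optimizes the uncertainty-weighted
#' focal+dice loss with AdamW on shuffled mini-batches, evaluating the
#' validation loss after every epoch. Training stops when the validation
#' loss has failed to improve by `min_delta` for `patience` consecutive
#' epochs (or at `max_epochs`), and the weights of the best validation
#' epoch are returned. All randomness (initialization, shuffling, dropout)
#' flows from `train_cfg$seed`, so runs are reproducible.
#'
#' @param train_batch,val_batch Annotated [make_windows()] batches with
#'   disjoint record provenance (the split is by patient).
#' @param config A [model_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A trained `vent_unet` with a `history` data frame (per-epoch
#'   train/validation loss and the learned sigmas) and `best_epoch`.
#' @export
train_unet <- function(train_batch, val_batch, config = model_config(),
                       loss_cfg = loss_config(), train_cfg = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(train_batch, "window_batch"),
            inherits(val_batch, "window_batch"))
  if (is.null(train_batch$targets) || is.null(val_batch$targets))
    stop("training requires annotated window batches", call. = FALSE)
  overlap <- intersect(unique(train_batch$record_ids),
                       unique(val_batch$record_ids))
  if (length(overlap))
    stop("patient leakage between train and validation: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  n_train <- dim(train_batch$inputs)[1]
  if (n_train < 1L || dim(val_batch$inputs)[1] < 1L)
    stop("empty batch", call. = FALSE)

  with_seed(train_cfg$seed, {
    params <- unet_init_params(config, loss_cfg)
    state <- adamw_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    hist <- list()
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(n_train)
      starts <- seq(1L, n_train, by = train_cfg$batch_size)
      tr_losses <- numeric(0)
      for (st in starts) {
        idx <- ord[st:min(n_train, st + train_cfg$batch_size - 1L)]
        mb <- slice_batch(train_batch, idx)
        fw <- unet_forward(params, config, mb$inputs, training = TRUE,
                           keep_cache = TRUE)
        ls <- unet_loss(fw, mb$targets, params$log_sig, loss_cfg)
        grads <- unet_backward(params, config, fw$cache, ls$dz_insp, ls$dz_exp)
        grads[["log_sig"]] <- ls$dsig
        stepped <- adamw_step(params, grads, state,
                              train_cfg$learning_rate, train_cfg$weight_decay)
        params <- stepped$params
        state <- stepped$state
        tr_losses <- c(tr_losses, ls$total)
      }
      vp <- forward_chunked(params, config, val_batch$inputs)
      vl <- unet_loss(vp, val_batch$targets, params$log_sig, loss_cfg,
                      want_grads = FALSE)
      sig <- sqrt(exp(params$log_sig))
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(tr_losses),
                                  val_loss = vl$total,
                                  sigma1 = sig[1], sigma2 = sig[2])
      if (verbose)
        message(sprintf("epoch %3d: train %.5f val %.5f (sigma %.3f/%.3f)",
                        epoch, mean(tr_losses), vl$total, sig[1], sig[2]))
      if (vl$total < best$loss - train_cfg$min_delta) {
        best <- list(loss = vl$total, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= train_cfg$patience) break
      }
    }
    structure(list(params = best$params, config = config,
                   loss_config = loss_cfg, train_config = train_cfg,
                   history = do.call(rbind, hist), best_epoch = best$epoch),
              class = "vent_unet")
  })
}

#' Post-process probability traces into onset events
#'
#' Candidate events are strict local maxima of each trace exceeding the
#' threshold (strictly). Candidates of the same type closer than `debounce`
#' samples are merged, keeping the highest-probability one. Between
#' consecutive inspiratory events only the single highest-probability
#' expiratory candidate is kept; expiratory candidates before the first or
#' after the last inspiratory event are kept only when unique in that open
#' segment. The result always satisfies the [onset_annotation()] pairing
#' invariants.
#'
#' @param p_insp,p_exp Numeric probability traces of equal length.
#' @param threshold Detection threshold (default 0.5; strictly greater-than).
#' @param debounce Merge radius in samples (default 5, i.e. 0.1 s at 50 Hz).
#' @param sample_rate Sampling rate (carried through for provenance).
#' @return An [onset_annotation()].
#' @export
postprocess_events <- function(p_insp, p_exp, threshold = 0.5, debounce = 5L,
                               sample_rate = 50) {
  stopifnot(length(p_insp) == length(p_exp))
  peaks <- function(p) {
    n <- length(p)
    if (n == 0L) return(integer(0))
    prev <- c(-Inf, p[-n]); nxt <- c(p[-1], -Inf)
    which(p > threshold & p > prev & p >= nxt)
  }
  nms <- function(cand, p) {
    if (!length(cand)) return(integer(0))
    ord <- cand[order(-p[cand], cand)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= debounce))
        kept <- c(kept, i)
    }
    sort(kept)
  }
  insp <- nms(peaks(p_insp), p_insp)
  expc <- nms(peaks(p_exp), p_exp)
  expc <- setdiff(expc, insp) # an expiratory onset cannot share its sample
  keep_exp <- integer(0)
  if (length(expc)) {
    seg <- findInterval(expc, insp)
    for (s in unique(seg)) {
      in_seg <- expc[seg == s]
      if (s >= 1L && s <= length(insp) - 1L) {
        keep_exp <- c(keep_exp, in_seg[which.max(p_exp[in_seg])])
      } else if (length(in_seg) == 1L) {
        keep_exp <- c(keep_exp, in_seg) # open segment: only if unique
      }
    }
  }
  onset_annotation(insp, sort(keep_exp))
}

#' Segment a full record with a trained U-Net
#'
#' Tiles the record into non-overlapping output spans (reflection-padded at
#' the edges), runs the network, stitches the per-window probabilities into
#' full-length traces, and post-processes them into onset events.
#'
#' @param model A trained `vent_unet`.
#' @param record A [vent_record()] of at least `output_len` samples.
#' @param threshold,debounce Passed to [postprocess_events()].
#' @return An object of class `vent_prediction`: full-length `p_insp` and
#'   `p_exp` traces and the post-processed `events` annotation.
#' @export
predict_record <- function(model, record, threshold = 0.5, debounce = 5L) {
  stopifnot(inherits(model, "vent_unet"), inherits(record, "vent_record"))
  cfg <- model$config
  wb <- make_windows(record, cfg$input_len, cfg$output_len)
  pr <- forward_chunked(model$params, cfg, wb$inputs)
  n <- length(record$flow)
  K <- dim(wb$inputs)[1]
  trace <- function(parr) {
    full <- numeric(K * cfg$output_len)
    for (k in seq_len(K))
      full[wb$out_starts[k] + seq_len(cfg$output_len) - 1L] <- parr[k, , 1L]
    full[seq_len(n)]
  }
  p1 <- trace(pr$p_insp)
  p2 <- trace(pr$p_exp)
  events <- postprocess_events(p1, p2, threshold, debounce, record$sample_rate)
  structure(list(p_insp = p1, p_exp = p2, events = events,
                 record_id = record$patient_id),
            class = "vent_prediction")
}

#' @export
print.vent_prediction <- function(x, ...) {
  cat(sprintf("<vent_prediction> record %s: %d inspiratory, %d expiratory onsets\n",
              x$record_id, length(x$events$insp_onsets), length(x$events$exp_onsets)))
  invisible(x)
}

#' Save / load a trained model
#'
#' Checkpoints the parameter arrays in R's native serialization alongside a
#' human-readable JSON sidecar of the architecture, loss and training
#' configurations plus the training history.
#'
#' @param model A `vent_unet`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` (for `save_model`) or the restored `vent_unet`
#'   (for `load_model`), invisibly resp. visibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "vent_unet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  jsonlite::write_json(
    list(config = unclass(model$config),
         loss_config = unclass(model$loss_config),
         train_config = if (!is.null(model$train_config)) unclass(model$train_config),
         best_epoch = model$best_epoch,
         history = model$history),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config[names(meta$config) %in%
                                             names(formals(model_config))])
  lc_args <- meta$loss_config[names(meta$loss_config) %in% names(formals(loss_config))]
  structure(list(params = readRDS(file.path(dir, "weights.rds")),
                 config = cfg,
                 loss_config = do.call(loss_config, lc_args),
                 history = meta$history,
                 best_epoch = meta$best_epoch %||% NA_integer_),
            class = "vent_unet")
}
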