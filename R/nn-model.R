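# The dual-head attention-gated 1-D U-Net. Parameters live in a flat named
# list of arrays; unet_forward returns per-layer caches that unet_backward
# walks in reverse. The architecture follows the standard attention U-Net
# template: an encoder of paired convolutions with LeakyReLU and max
# pooling (feature depth doubling per level), a dilated-convolution
# bottleneck with dropout, a decoder of transposed-convolution upsampling
# with additively attention-gated skip concatenations, a center crop to the
# output span, and two task heads (inspiratory / expiratory onset), each a
# convolution, layer normalization, dropout, a position-wise dense layer
# with GELU, and a 1-channel dense layer with terminal sigmoid.

#' U-Net architecture configuration
#'
#' @param depth Number of encoder levels (default 4); `input_len` must be
#'   divisible by `2^depth`.
#' @param base_filters Filters in the first encoder level (default 32),
#'   doubling per level.
#' @param kernel_size Convolution kernel length (odd; default 7).
#' @param convs_per_block Convolutions per encoder/decoder block (default 2).
#' @param bottleneck_dilations Dilation rates of the bottleneck
#'   convolutions (default `c(1, 2, 4)`).
#' @param dropout_bottleneck,dropout_head Dropout rates (defaults 0.3, 0.2).
#' @param leaky_slope Negative slope of LeakyReLU (default 0.01).
#' @param input_len,output_len Input window and centered output span
#'   lengths in samples (defaults 352 / 176).
#' @param channels_in Input channels (pressure, flow; default 2).
#' @return An object of class `model_config`.
#' @export
model_config <- function(depth = 4L, base_filters = 32L, kernel_size = 7L,
                         convs_per_block = 2L, bottleneck_dilations = c(1L, 2L, 4L),
                         dropout_bottleneck = 0.3, dropout_head = 0.2,
                         leaky_slope = 0.01, input_len = 352L, output_len = 176L,
                         channels_in = 2L) {
  stopifnot(depth >= 1L, base_filters >= 1L, kernel_size %% 2L == 1L,
            convs_per_block >= 1L, length(bottleneck_dilations) >= 1L,
            output_len <= input_len)
  if (input_len %% (2L^depth) != 0L)
    stop(sprintf("input_len %d is not divisible by 2^depth = %d",
                 input_len, 2L^depth), call. = FALSE)
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size),
                 convs_per_block = as.integer(convs_per_block),
                 bottleneck_dilations = as.integer(bottleneck_dilations),
                 dropout_bottleneck = dropout_bottleneck,
                 dropout_head = dropout_head, leaky_slope = leaky_slope,
                 input_len = as.integer(input_len),
                 output_len = as.integer(output_len),
                 channels_in = as.integer(channels_in)),
            class = "model_config")
}

#' Composite loss configuration
#'
#' The training objective is an uncertainty-weighted combination of a focal
#' and a dice term,
#' `L = L_focal / (2 sigma1^2) + L_dice / (2 sigma2^2) + log sigma1 + log sigma2`,
#' with the task-uncertainty parameters learned jointly with the network
#' (parameterized as `log sigma^2`, initialized at 0). The logarithmic
#' terms keep the sigmas from diverging.
#'
#' @param alpha Focal balancing factor (default 0.25).
#' @param gamma Focal focusing strength (default 2).
#' @param epsilon Dice stability constant (default 1e-6).
#' @param log_sigma_sq Initial values of `log sigma^2` for the two terms.
#' @param pairing `"by_loss"` (default; one sigma per loss term, as the
#'   equation reads) or `"by_head"` (one sigma per task head, weighting
#'   each head's focal+dice sum).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2.0, epsilon = 1e-6,
                        log_sigma_sq = c(0, 0),
                        pairing = c("by_loss", "by_head")) {
  stopifnot(gamma >= 0, epsilon > 0, is.finite(log_sigma_sq),
            length(log_sigma_sq) == 2L)
  structure(list(alpha = alpha, gamma = gamma, epsilon = epsilon,
                 log_sigma_sq = as.numeric(log_sigma_sq),
                 pairing = match.arg(pairing)),
            class = "loss_config")
}

#' Training configuration
#'
#' @param learning_rate AdamW initial learning rate (default 5e-4).
#' @param weight_decay Decoupled weight decay on convolution/dense weight
#'   matrices (default 1e-2).
#' @param batch_size Windows per mini-batch (default 32).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param min_delta Minimum validation-loss improvement (default 1e-4).
#' @param max_epochs Epoch cap.
#' @param seed Integer seed driving weight init, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 1e-2,
                         batch_size = 32L, patience = 10L, min_delta = 1e-4,
                         max_epochs = 100L, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1L,
            patience >= 1L, min_delta > 0, max_epochs >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), min_delta = min_delta,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

# Encoder/decoder channel widths per level and the bottleneck width.
unet_channels <- function(cfg) {
  ch <- cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)
  list(ch = ch, bott = cfg$base_filters * 2L^cfg$depth)
}

he_conv <- function(k, c_in, c_out)
  array(stats::rnorm(k * c_in * c_out, 0, sqrt(2 / (k * c_in))), c(k, c_in, c_out))
he_mat <- function(c_in, c_out)
  matrix(stats::rnorm(c_in * c_out, 0, sqrt(2 / c_in)), c_in, c_out)

# He-initialized flat parameter list. Draws from the active RNG stream.
unet_init_params <- function(cfg, loss_cfg = loss_config()) {
  k <- cfg$kernel_size
  chs <- unet_channels(cfg)
  ch <- chs$ch; chb <- chs$bott
  p <- list()
  c_prev <- cfg$channels_in
  for (i in seq_len(cfg$depth)) {
    for (j in seq_len(cfg$convs_per_block)) {
      c_in <- if (j == 1L) c_prev else ch[i]
      p[[sprintf("enc%d.c%d.W", i, j)]] <- he_conv(k, c_in, ch[i])
      p[[sprintf("enc%d.c%d.b", i, j)]] <- rep(0, ch[i])
    }
    c_prev <- ch[i]
  }
  for (r in seq_along(cfg$bottleneck_dilations)) {
    c_in <- if (r == 1L) ch[cfg$depth] else chb
    p[[sprintf("bott%d.W", r)]] <- he_conv(k, c_in, chb)
    p[[sprintf("bott%d.b", r)]] <- rep(0, chb)
  }
  for (i in rev(seq_len(cfg$depth))) {
    c_in <- if (i == cfg$depth) chb else ch[i + 1L]
    p[[sprintf("dec%d.up.W1", i)]] <- he_mat(c_in, ch[i])
    p[[sprintf("dec%d.up.W2", i)]] <- he_mat(c_in, ch[i])
    p[[sprintf("dec%d.up.b", i)]] <- rep(0, ch[i])
    c_int <- max(1L, ch[i] %/% 2L)
    p[[sprintf("dec%d.att.Wt", i)]] <- he_conv(1L, ch[i], c_int)
    p[[sprintf("dec%d.att.Wp", i)]] <- he_conv(1L, ch[i], c_int)
    p[[sprintf("dec%d.att.bp", i)]] <- rep(0, c_int)
    p[[sprintf("dec%d.att.Wpsi", i)]] <- he_conv(1L, c_int, 1L)
    p[[sprintf("dec%d.att.bpsi", i)]] <- rep(0, 1)
    for (j in seq_len(cfg$convs_per_block)) {
      c_in_j <- if (j == 1L) 2L * ch[i] else ch[i]
      p[[sprintf("dec%d.c%d.W", i, j)]] <- he_conv(k, c_in_j, ch[i])
      p[[sprintf("dec%d.c%d.b", i, j)]] <- rep(0, ch[i])
    }
  }
  for (h in 1:2) {
    p[[sprintf("head%d.conv.W", h)]] <- he_conv(k, ch[1], ch[1])
    p[[sprintf("head%d.conv.b", h)]] <- rep(0, ch[1])
    p[[sprintf("head%d.ln.gamma", h)]] <- rep(1, ch[1])
    p[[sprintf("head%d.ln.beta", h)]] <- rep(0, ch[1])
    p[[sprintf("head%d.d1.W", h)]] <- he_conv(1L, ch[1], ch[1])
    p[[sprintf("head%d.d1.b", h)]] <- rep(0, ch[1])
    p[[sprintf("head%d.d2.W", h)]] <- he_conv(1L, ch[1], 1L)
    p[[sprintf("head%d.d2.b", h)]] <- rep(0, 1)
  }
  p[["log_sig"]] <- loss_cfg$log_sigma_sq
  p
}

#' Build an (untrained) breath-segmentation U-Net
#'
#' @param config A [model_config()].
#' @param loss_cfg A [loss_config()]; its initial `log sigma^2` values are
#'   placed among the trainable parameters.
#' @param seed Seed for He weight initialization.
#' @return An object of class `vent_unet`.
#' @export
build_model <- function(config = model_config(), loss_cfg = loss_config(),
                        seed = 1L) {
  params <- with_seed(seed, unet_init_params(config, loss_cfg))
  structure(list(params = params, config = config, loss_config = loss_cfg,
                 history = NULL, best_epoch = NA_integer_),
            class = "vent_unet")
}

#' @export
print.vent_unet <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<vent_unet> depth %d, base %d filters, %s parameters%s\n",
              x$config$depth, x$config$base_filters, format(n_par, big.mark = ","),
              if (is.null(x$history)) " (untrained)"
              else sprintf(", best epoch %d", x$best_epoch)))
  invisible(x)
}

# Full forward pass. x: (N, input_len, channels_in). Returns sigmoid
# probabilities and logits for both heads, the pre-crop trunk feature map,
# and (if keep_cache) everything needed for the backward pass.
unet_forward <- function(params, cfg, x, training = FALSE, keep_cache = FALSE) {
  cc <- list()
  h <- x
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    blk <- list()
    for (j in seq_len(cfg$convs_per_block)) {
      cv <- conv1d_fwd(h, params[[sprintf("enc%d.c%d.W", i, j)]],
                       params[[sprintf("enc%d.c%d.b", i, j)]])
      ac <- leaky_relu_fwd(cv$y, cfg$leaky_slope)
      h <- ac$y
      blk[[j]] <- list(conv = cv$cache, act = ac$cache)
    }
    skips[[i]] <- h
    pl <- maxpool_fwd(h)
    h <- pl$y
    cc[[sprintf("enc%d", i)]] <- list(convs = blk, pool = pl$cache)
  }
  for (r in seq_along(cfg$bottleneck_dilations)) {
    cv <- conv1d_fwd(h, params[[sprintf("bott%d.W", r)]],
                     params[[sprintf("bott%d.b", r)]],
                     dilation = cfg$bottleneck_dilations[r])
    ac <- leaky_relu_fwd(cv$y, cfg$leaky_slope)
    h <- ac$y
    cc[[sprintf("bott%d", r)]] <- list(conv = cv$cache, act = ac$cache)
  }
  dr <- dropout_fwd(h, cfg$dropout_bottleneck, training)
  h <- dr$y
  cc[["bott_drop"]] <- dr$cache
  for (i in rev(seq_len(cfg$depth))) {
    up <- convtr_fwd(h, params[[sprintf("dec%d.up.W1", i)]],
                     params[[sprintf("dec%d.up.W2", i)]],
                     params[[sprintf("dec%d.up.b", i)]])
    att <- attgate_fwd(skips[[i]], up$y, list(
      Wt = params[[sprintf("dec%d.att.Wt", i)]],
      Wp = params[[sprintf("dec%d.att.Wp", i)]],
      bp = params[[sprintf("dec%d.att.bp", i)]],
      Wpsi = params[[sprintf("dec%d.att.Wpsi", i)]],
      bpsi = params[[sprintf("dec%d.att.bpsi", i)]]))
    ct <- concat_fwd(att$y, up$y)
    h <- ct$y
    blk <- list()
    for (j in seq_len(cfg$convs_per_block)) {
      cv <- conv1d_fwd(h, params[[sprintf("dec%d.c%d.W", i, j)]],
                       params[[sprintf("dec%d.c%d.b", i, j)]])
      ac <- leaky_relu_fwd(cv$y, cfg$leaky_slope)
      h <- ac$y
      blk[[j]] <- list(conv = cv$cache, act = ac$cache)
    }
    cc[[sprintf("dec%d", i)]] <- list(up = up$cache, att = att$cache,
                                      cat = ct$cache, convs = blk)
  }
  trunk <- h
  cr <- crop_fwd(trunk, cfg$output_len)
  cc[["crop"]] <- cr$cache
  logits <- vector("list", 2L)
  probs <- vector("list", 2L)
  for (hd in 1:2) {
    cv <- conv1d_fwd(cr$y, params[[sprintf("head%d.conv.W", hd)]],
                     params[[sprintf("head%d.conv.b", hd)]])
    ln <- layernorm_fwd(cv$y, params[[sprintf("head%d.ln.gamma", hd)]],
                        params[[sprintf("head%d.ln.beta", hd)]])
    dr_h <- dropout_fwd(ln$y, cfg$dropout_head, training)
    d1 <- conv1d_fwd(dr_h$y, params[[sprintf("head%d.d1.W", hd)]],
                     params[[sprintf("head%d.d1.b", hd)]])
    ge <- gelu_fwd(d1$y)
    d2 <- conv1d_fwd(ge$y, params[[sprintf("head%d.d2.W", hd)]],
                     params[[sprintf("head%d.d2.b", hd)]])
    sg <- sigmoid_fwd(d2$y)
    logits[[hd]] <- d2$y
    probs[[hd]] <- sg$y
    cc[[sprintf("head%d", hd)]] <- list(conv = cv$cache, ln = ln$cache,
                                        drop = dr_h$cache, d1 = d1$cache,
                                        gelu = ge$cache, d2 = d2$cache,
                                        sig = sg$cache)
  }
  list(p_insp = probs[[1]], p_exp = probs[[2]],
       z_insp = logits[[1]], z_exp = logits[[2]],
       trunk = if (keep_cache) trunk else NULL,
       cache = if (keep_cache) cc else NULL)
}

# Backward through one head (from its logit gradient) down to the cropped
# trunk input; returns the gradient there plus head parameter gradients.
head_backward <- function(params, cfg, cc, hd, dz) {
  hc <- cc[[sprintf("head%d", hd)]]
  g <- list()
  b2 <- conv1d_bwd(dz, hc$d2)
  g[[sprintf("head%d.d2.W", hd)]] <- b2$dW
  g[[sprintf("head%d.d2.b", hd)]] <- b2$db
  dge <- gelu_bwd(b2$dx, hc$gelu)
  b1 <- conv1d_bwd(dge, hc$d1)
  g[[sprintf("head%d.d1.W", hd)]] <- b1$dW
  g[[sprintf("head%d.d1.b", hd)]] <- b1$db
  ddr <- dropout_bwd(b1$dx, hc$drop)
  bl <- layernorm_bwd(ddr, hc$ln)
  g[[sprintf("head%d.ln.gamma", hd)]] <- bl$dgamma
  g[[sprintf("head%d.ln.beta", hd)]] <- bl$dbeta
  bc <- conv1d_bwd(bl$dx, hc$conv)
  g[[sprintf("head%d.conv.W", hd)]] <- bc$dW
  g[[sprintf("head%d.conv.b", hd)]] <- bc$db
  list(dcrop = bc$dx, grads = g)
}

# Full backward pass from per-head logit gradients; returns the flat
# gradient list (no entry for log_sig, whose gradient is analytic in the
# loss and handled by the training loop).
unet_backward <- function(params, cfg, cc, dz_insp, dz_exp) {
  g <- list()
  hb1 <- head_backward(params, cfg, cc, 1L, dz_insp)
  hb2 <- head_backward(params, cfg, cc, 2L, dz_exp)
  g <- c(g, hb1$grads, hb2$grads)
  dh <- crop_bwd(hb1$dcrop + hb2$dcrop, cc[["crop"]])
  for (i in seq_len(cfg$depth)) {
    dc <- cc[[sprintf("dec%d", i)]]
    for (j in rev(seq_len(cfg$convs_per_block))) {
      dh <- leaky_relu_bwd(dh, dc$convs[[j]]$act)
      bj <- conv1d_bwd(dh, dc$convs[[j]]$conv)
      g[[sprintf("dec%d.c%d.W", i, j)]] <- bj$dW
      g[[sprintf("dec%d.c%d.b", i, j)]] <- bj$db
      dh <- bj$dx
    }
    sp <- concat_bwd(dh, dc$cat)
    ab <- attgate_bwd(sp$da, dc$att, NULL)
    g[[sprintf("dec%d.att.Wt", i)]] <- ab$dWt
    g[[sprintf("dec%d.att.Wp", i)]] <- ab$dWp
    g[[sprintf("dec%d.att.bp", i)]] <- ab$dbp
    g[[sprintf("dec%d.att.Wpsi", i)]] <- ab$dWpsi
    g[[sprintf("dec%d.att.bpsi", i)]] <- ab$dbpsi
    dup_out <- sp$db + ab$dg
    ub <- convtr_bwd(dup_out, dc$up)
    g[[sprintf("dec%d.up.W1", i)]] <- ub$dW1
    g[[sprintf("dec%d.up.W2", i)]] <- ub$dW2
    g[[sprintf("dec%d.up.b", i)]] <- ub$db
    # gradient into the encoder skip accumulates later, at the encoder walk
    cc[[sprintf("enc%d", i)]]$dskip <- ab$dx
    dh <- ub$dx
  }
  dh <- dropout_bwd(dh, cc[["bott_drop"]])
  for (r in rev(seq_along(cfg$bottleneck_dilations))) {
    bc <- cc[[sprintf("bott%d", r)]]
    dh <- leaky_relu_bwd(dh, bc$act)
    bj <- conv1d_bwd(dh, bc$conv)
    g[[sprintf("bott%d.W", r)]] <- bj$dW
    g[[sprintf("bott%d.b", r)]] <- bj$db
    dh <- bj$dx
  }
  for (i in rev(seq_len(cfg$depth))) {
    ec <- cc[[sprintf("enc%d", i)]]
    dh <- maxpool_bwd(dh, ec$pool) + ec$dskip
    for (j in rev(seq_len(cfg$convs_per_block))) {
      dh <- leaky_relu_bwd(dh, ec$convs[[j]]$act)
      bj <- conv1d_bwd(dh, ec$convs[[j]]$conv)
      g[[sprintf("enc%d.c%d.W", i, j)]] <- bj$dW
      g[[sprintf("enc%d.c%d.b", i, j)]] <- bj$db
      dh <- bj$dx
    }
  }
  g
}

# ---- losses -----------------------------------------------------------------

clip_prob <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Focal loss
#'
#' Mean over elements of `-alpha (1 - pt)^gamma log(pt)` where `pt` is the
#' predicted probability of the true class (`p` where the target is 1,
#' `1 - p` where it is 0). With `gamma = 0`, `alpha = 1` this reduces to
#' mean binary cross-entropy. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param p Predicted probabilities.
#' @param g Binary targets of the same shape.
#' @param alpha Balancing factor.
#' @param gamma Focusing strength (>= 0).
#' @return Scalar loss.
#' @export
focal_loss <- function(p, g, alpha = 0.25, gamma = 2.0) {
  if (length(p) != length(g)) stop("shape mismatch", call. = FALSE)
  p <- clip_prob(as.vector(p)); g <- as.vector(g)
  pt <- ifelse(g == 1, p, 1 - p)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

# d(focal mean)/dp, elementwise.
focal_grad <- function(p, g, alpha = 0.25, gamma = 2.0) {
  pc <- clip_prob(p)
  pt <- ifelse(g == 1, pc, 1 - pc)
  dpt <- -alpha * (-gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) * (gamma > 0) +
                     (1 - pt)^gamma / pt)
  sgn <- ifelse(g == 1, 1, -1)
  dpt * sgn / length(p)
}

#' Dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)`: one minus a soft
#' overlap coefficient, encouraging temporal alignment of predicted event
#' mass with the ground truth. Zero for exact binary agreement and for the
#' all-zero / all-zero case.
#'
#' @param p Predicted probabilities.
#' @param g Binary targets of the same shape.
#' @param epsilon Stability constant.
#' @return Scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(p, g, epsilon = 1e-6) {
  if (length(p) != length(g)) stop("shape mismatch", call. = FALSE)
  p <- as.vector(p); g <- as.vector(g)
  1 - (2 * sum(p * g) + epsilon) / (sum(p) + sum(g) + epsilon)
}

dice_grad <- function(p, g, epsilon = 1e-6) {
  S <- sum(p) + sum(g) + epsilon
  num <- 2 * sum(p * g) + epsilon
  -(2 * g * S - num) / S^2
}

#' Uncertainty-weighted total loss
#'
#' `L_focal / (2 sigma1^2) + L_dice / (2 sigma2^2) + log sigma1 + log sigma2`
#' with `sigma^2 = exp(log_sigma_sq)`. At `sigma1 = sigma2 = 1` this is the
#' plain average of the two components; minimizing over a sigma alone gives
#' the stationary point `sigma^2 = L`.
#'
#' @param loss_focal,loss_dice Component losses (scalars).
#' @param loss_cfg A [loss_config()]; its `log_sigma_sq` supplies the
#'   current uncertainty parameters.
#' @return Scalar total loss.
#' @export
total_loss <- function(loss_focal, loss_dice, loss_cfg = loss_config()) {
  s <- loss_cfg$log_sigma_sq
  0.5 * exp(-s[1]) * loss_focal + 0.5 * exp(-s[2]) * loss_dice +
    0.5 * (s[1] + s[2])
}
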