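# Gradient-weighted class activation mapping for 1-D onset predictions.
# The target scalar is the pre-sigmoid logit of the chosen head at the
# chosen output timestep; gradients are taken with respect to the last
# convolution of the shared trunk (the final decoder convolution, before
# the center crop), which here already sits at full input resolution.

#' Grad-CAM heatmap for a single onset prediction
#'
#' Runs one normalized input window through the model, backpropagates the
#' selected head's pre-sigmoid logit at the selected output timestep to the
#' last shared-trunk convolution, forms per-channel weights as
#' time-averaged gradients, and returns the rectified, max-normalized
#' weighted sum of the feature maps over the full input window.
#'
#' @param model A trained `vent_unet`.
#' @param window Normalized input window, `input_len x 2` matrix (or
#'   `1 x input_len x 2` array), e.g. one slice of [make_windows()] inputs.
#' @param head `"insp"` or `"exp"`.
#' @param timestep Output-span timestep (1-based, within
#'   `1..output_len`) whose prediction is explained.
#' @return An object of class `cam_result`: `heat` (length `input_len`,
#'   in `[0, 1]`, max 1 unless all activations vanish), `target_head`,
#'   `target_timestep`, and `predicted_probability`.
#' @export
grad_cam <- function(model, window, head = c("insp", "exp"), timestep) {
  stopifnot(inherits(model, "vent_unet"))
  head <- match.arg(head)
  cfg <- model$config
  if (is.matrix(window))
    window <- array(window, c(1L, nrow(window), ncol(window)))
  stopifnot(length(dim(window)) == 3L, dim(window)[2] == cfg$input_len)
  if (timestep < 1L || timestep > cfg$output_len)
    stop("timestep outside the output span", call. = FALSE)

  fw <- unet_forward(model$params, cfg, window, training = FALSE,
                     keep_cache = TRUE)
  hd <- if (head == "insp") 1L else 2L
  prob <- if (hd == 1L) fw$p_insp[1L, timestep, 1L] else fw$p_exp[1L, timestep, 1L]

  dz <- array(0, c(1L, cfg$output_len, 1L))
  dz[1L, timestep, 1L] <- 1
  hb <- head_backward(model$params, cfg, fw$cache, hd, dz)
  dA <- crop_bwd(hb$dcrop, fw$cache[["crop"]]) # (1, input_len, C_trunk)
  A <- fw$trunk

  C <- dim(A)[3]
  w <- vapply(seq_len(C), function(c) mean(dA[1L, , c]), numeric(1))
  heat <- rowSums(sweep(matrix(A[1L, , ], ncol = C), 2, w, "*"))
  heat <- pmax(heat, 0)
  mx <- max(heat)
  if (mx <= 0) {
    warning("all-zero Grad-CAM activations; returning flat zero heat",
            call. = FALSE)
  } else {
    heat <- heat / mx
  }
  structure(list(heat = heat, target_head = head,
                 target_timestep = as.integer(timestep),
                 predicted_probability = prob),
            class = "cam_result")
}

#' @export
print.cam_result <- function(x, ...) {
  cat(sprintf("<cam_result> %s head, timestep %d (p = %.3f), peak heat at input sample %d\n",
              x$target_head, x$target_timestep, x$predicted_probability,
              which.max(x$heat)))
  invisible(x)
}
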