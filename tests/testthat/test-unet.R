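test_that("focal loss matches its closed form", {
  set.seed(2)
  p <- runif(200, 0.01, 0.99)
  g <- rbinom(200, 1, 0.3)
  # gamma = 0, alpha = 1 reduces to mean binary cross-entropy
  bce <- mean(-(g * log(p) + (1 - g) * log(1 - p)))
  expect_equal(focal_loss(p, g, alpha = 1, gamma = 0), bce, tolerance = 1e-12)
  # single element, hand evaluation of -alpha (1-pt)^gamma log pt
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 2), 0.25 * log(2),
               tolerance = 1e-12)
  # perfect prediction saturates to ~0 after clipping
  expect_lt(focal_loss(g, g), 1e-5)
  expect_error(focal_loss(c(0.5, 0.5), 1), "shape mismatch")
})

test_that("dice loss is a soft overlap complement", {
  g <- c(rep(0, 175), 1)
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-6)
  expect_equal(dice_loss(rep(0, 176), rep(0, 176)), 0)
  # total disagreement: 1 - eps/(175 + 1 + eps)
  expect_equal(dice_loss(1 - g, g), 1 - 1e-6 / (176 + 1e-6), tolerance = 1e-9)
  expect_true(dice_loss(runif(50), rbinom(50, 1, 0.5)) >= 0)
})

test_that("total loss combines components under learned uncertainties", {
  lc1 <- loss_config(log_sigma_sq = c(0, 0))
  expect_equal(total_loss(0.8, 0.4, lc1), 0.6) # sigma 1: plain average
  lc_e <- loss_config(log_sigma_sq = c(2, 2))  # sigma = e
  expect_equal(total_loss(0, 0, lc_e), 2)
  # monotone increasing in each component at fixed sigma
  expect_gt(total_loss(0.9, 0.4, lc1), total_loss(0.8, 0.4, lc1))
  expect_gt(total_loss(0.8, 0.5, lc1), total_loss(0.8, 0.4, lc1))
})

test_that("gradient descent on the uncertainties converges to sigma^2 = L", {
  # minimize a/(2 sigma^2) + log sigma in s = log sigma^2:
  # d/ds [0.5 a e^{-s} + 0.5 s] = 0 at e^s = a
  for (a in c(0.5, 1, 2)) {
    s <- 0
    for (i in 1:4000) s <- s - 0.05 * (0.5 - 0.5 * exp(-s) * a)
    expect_equal(exp(s), a, tolerance = 1e-4)
  }
})

test_that("the network maps windows to bounded dual-head outputs", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 3)
  x <- array(rnorm(4 * cfg$input_len * 2), c(4, cfg$input_len, 2))
  fw <- ventseg:::unet_forward(m$params, cfg, x)
  expect_equal(dim(fw$p_insp), c(4, cfg$output_len, 1))
  expect_equal(dim(fw$p_exp), c(4, cfg$output_len, 1))
  expect_true(all(fw$p_insp > 0 & fw$p_insp < 1))
  expect_true(all(fw$p_exp > 0 & fw$p_exp < 1))
  expect_error(model_config(depth = 4, input_len = 100, output_len = 50),
               "divisible")
})

test_that("pooling halves the time axis per level", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 3)
  x <- array(rnorm(2 * 32 * 2), c(2, 32, 2))
  fw <- ventseg:::unet_forward(m$params, cfg, x, keep_cache = TRUE)
  # deepest feature length: input_len / 2^depth (352/16 = 22 at full scale)
  bott <- fw$cache[["bott1"]]$conv
  expect_equal(bott$L, 32 / 2^cfg$depth)
})

test_that("a zero-initialized attention gate is uniform over time", {
  set.seed(1)
  x <- array(rnorm(2 * 16 * 4), c(2, 16, 4))
  p <- list(Wt = array(0, c(1, 4, 2)), Wp = array(0, c(1, 4, 2)),
            bp = rep(0, 2), Wpsi = array(0, c(1, 2, 1)), bpsi = 0.7)
  out <- ventseg:::attgate_fwd(x, x, p)
  expect_equal(as.vector(out$coeff), rep(plogis(0.7), 2 * 16), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_model_config()
  lc <- loss_config()
  ns <- asNamespace("ventseg")
  params <- ns$with_seed(7, ns$unet_init_params(cfg, lc))
  set.seed(42)
  x <- array(rnorm(2 * 32 * 2), c(2, 32, 2))
  targ <- array(0, c(2, 16, 2)); targ[1, 5, 1] <- 1; targ[2, 11, 2] <- 1
  loss_of <- function(p) {
    fw <- ns$unet_forward(p, cfg, x)
    ns$unet_loss(fw, targ, p$log_sig, lc, want_grads = FALSE)$total
  }
  fw <- ns$unet_forward(params, cfg, x, keep_cache = TRUE)
  ls <- ns$unet_loss(fw, targ, params$log_sig, lc)
  grads <- ns$unet_backward(params, cfg, fw$cache, ls$dz_insp, ls$dz_exp)
  grads$log_sig <- ls$dsig
  eps <- 1e-6
  check <- c("enc1.c1.W", "bott2.W", "dec1.att.Wpsi", "dec2.up.W1",
             "head1.ln.gamma", "head2.d2.W", "head2.d2.b", "log_sig")
  set.seed(1)
  for (nm in check) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("by-head loss pairing weights each task separately", {
  cfg <- tiny_model_config()
  ns <- asNamespace("ventseg")
  params <- ns$with_seed(7, ns$unet_init_params(cfg, loss_config()))
  set.seed(3)
  x <- array(rnorm(2 * 32 * 2), c(2, 32, 2))
  targ <- array(0, c(2, 16, 2)); targ[1, 5, 1] <- 1
  fw <- ns$unet_forward(params, cfg, x)
  lc_bh <- loss_config(pairing = "by_head", log_sigma_sq = c(0.3, -0.2))
  got <- ns$unet_loss(fw, targ, lc_bh$log_sigma_sq, lc_bh, want_grads = FALSE)
  L1 <- focal_loss(fw$p_insp, targ[, , 1], 0.25, 2) +
    dice_loss(fw$p_insp, targ[, , 1])
  L2 <- focal_loss(fw$p_exp, targ[, , 2], 0.25, 2) +
    dice_loss(fw$p_exp, targ[, , 2])
  want <- 0.5 * exp(-0.3) * L1 + 0.5 * exp(0.2) * L2 + 0.5 * (0.3 - 0.2)
  expect_equal(got$total, want, tolerance = 1e-12)
})

test_that("training stops early, keeps best weights, and is reproducible", {
  cfg <- tiny_model_config()
  cohort <- synth_cohort(noise_free_sim(n_patients = 2, breaths = 6, seed = 3))
  # tiny windows for the tiny architecture
  wb <- lapply(cohort, make_windows, input_len = 32L, output_len = 16L)
  tc <- train_config(max_epochs = 4, patience = 1, min_delta = 1e9, seed = 5,
                     batch_size = 8)
  m <- train_unet(wb[[1]], wb[[2]], cfg, loss_config(), tc)
  # an improvement of min_delta = 1e9 is unattainable: epoch 1 is best and
  # patience 1 stops after epoch 2
  expect_equal(nrow(m$history), 2L)
  expect_equal(m$best_epoch, 1L)

  tc2 <- train_config(max_epochs = 2, seed = 5, batch_size = 8)
  a <- train_unet(wb[[1]], wb[[2]], cfg, loss_config(), tc2)
  b <- train_unet(wb[[1]], wb[[2]], cfg, loss_config(), tc2)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)

  expect_error(train_unet(wb[[1]], wb[[1]], cfg, loss_config(), tc2),
               "leakage")
})

test_that("postprocessing enforces threshold, debounce and pairing rules", {
  n <- 300
  flat <- rep(0.4, n)
  none <- postprocess_events(flat, flat)
  expect_length(none$insp_onsets, 0)

  p_i <- rep(0.01, n); p_e <- rep(0.01, n)
  p_i[c(100, 102)] <- c(0.9, 0.7)  # two nearby inspiratory candidates
  p_i[200] <- 0.95
  p_e[c(130, 160)] <- c(0.8, 0.6)  # two expiratory candidates in one interval
  ev <- postprocess_events(p_i, p_e, debounce = 5)
  expect_equal(ev$insp_onsets, c(100L, 200L)) # debounced to the higher peak
  expect_equal(ev$exp_onsets, 130L)           # max-probability rule

  # expiratory candidates in an open leading segment survive only if unique
  p_e2 <- rep(0.01, n); p_e2[c(20, 40)] <- c(0.8, 0.7)
  p_i2 <- rep(0.01, n); p_i2[250] <- 0.9
  ev2 <- postprocess_events(p_i2, p_e2)
  expect_length(ev2$exp_onsets, 0)
  p_e2[40] <- 0.01
  ev3 <- postprocess_events(p_i2, p_e2)
  expect_equal(ev3$exp_onsets, 20L)
})

test_that("postprocessed events always satisfy annotation invariants", {
  set.seed(9)
  for (i in 1:25) {
    n <- 400
    p_i <- pmin(pmax(stats::filter(runif(n, 0, 1.2), rep(1 / 3, 3),
                                   circular = TRUE), 0), 1)
    p_e <- pmin(pmax(stats::filter(runif(n, 0, 1.2), rep(1 / 3, 3),
                                   circular = TRUE), 0), 1)
    expect_silent(ev <- postprocess_events(as.numeric(p_i), as.numeric(p_e)))
    expect_s3_class(ev, "onset_annotation") # constructor validates pairing
  }
})

test_that("prediction stitches full-length probability traces", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 11)
  rec <- vent_record("p", rnorm(80), rnorm(80))
  pr <- predict_record(m, rec)
  expect_length(pr$p_insp, 80)
  expect_length(pr$p_exp, 80)
  expect_true(all(pr$p_insp >= 0 & pr$p_insp <= 1))
  expect_error(predict_record(m, vent_record("p", rnorm(8), rnorm(8))),
               "shorter than")
})
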