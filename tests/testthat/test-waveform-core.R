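test_that("window_samples converts durations to sample counts", {
  expect_identical(window_samples(7.04, 50), 352L)
  expect_identical(window_samples(3.52, 50), 176L)
  expect_identical(window_samples(0.02, 50), 1L)
  expect_error(window_samples(0.015, 50), "integral")
  expect_error(window_samples(-1, 50), "positive")
})

test_that("normalize_window z-scores per channel with degenerate guard", {
  w <- cbind(rep(10, 8), rep(c(-1, 1), 4))
  z <- normalize_window(w)
  expect_true(all(z[, 1] == 0))          # constant channel -> zeros
  expect_equal(z[, 2], rep(c(-1, 1), 4)) # two-point set has population sd 1
  set.seed(1)
  z2 <- normalize_window(cbind(rnorm(352, 20, 7), runif(352, -60, 60)))
  expect_lt(max(abs(colMeans(z2))), 1e-9)
  sd_pop <- apply(z2, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(sd_pop, c(1, 1), tolerance = 1e-6)
})

test_that("records validate length, time step and annotation bounds", {
  expect_error(vent_record("p", 1:3, 1:4), "identical length")
  expect_error(vent_record("p", 1:3, 1:3, time = c(0, 0.02, 0.05)),
               "non-uniform time step at index 3")
  r <- vent_record("p", c(10, 11, 12), c(0, 30, -20))
  expect_s3_class(r, "vent_record")
  expect_equal(r$time, c(0, 0.02, 0.04))
  expect_error(
    vent_record("p", 1:3, 1:3,
                annotation = onset_annotation(5L, integer(0))),
    "beyond record bounds")
})

test_that("onset annotations enforce ordering and pairing invariants", {
  expect_error(onset_annotation(c(10, 10)), "strictly increasing")
  expect_error(onset_annotation(c(10, 100), c(20, 30)),
               "more than one expiratory onset")
  expect_error(onset_annotation(10, 10), "strictly after")
  a <- onset_annotation(c(10, 100), c(50, 150), c("normal", "pva"))
  expect_length(a$insp_onsets, 2)
  # a single expiratory onset may precede the first inspiratory onset
  expect_silent(onset_annotation(c(50, 100), c(10, 70)))
})

test_that("CSV round trip preserves numeric columns and annotations", {
  cfg <- noise_free_sim(n_patients = 1, breaths = 10, asynchrony = 0.4)
  rec <- synth_cohort(cfg)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$flow, rec$flow, tolerance = 1e-12)
  expect_equal(back$pressure, rec$pressure, tolerance = 1e-12)
  expect_equal(back$sample_rate, 50)
  expect_equal(back$annotation$insp_onsets, rec$annotation$insp_onsets)
  expect_equal(back$annotation$exp_onsets, rec$annotation$exp_onsets)
  expect_equal(back$annotation$breath_types, rec$annotation$breath_types)
})

test_that("read_record rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,flow", "0,1", "0.02,2"), path)
  expect_error(read_record(path), "missing required column")
  writeLines(c("time,pressure,flow", "0,5,1", "0.02,5,2", "0.02,5,3"), path)
  expect_error(read_record(path, sample_rate = 50), "non-uniform time step")
})

test_that("read_record infers 50 Hz from 0.02 s timestamps", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = (0:99) / 50, pressure = rnorm(100), flow = rnorm(100))
  data.table::fwrite(df, path)
  expect_equal(read_record(path)$sample_rate, 50)
})

test_that("make_windows tiles output spans and places labels", {
  ann <- onset_annotation(101L, 150L) # 1-based
  rec <- vent_record("p", rnorm(352), rnorm(352), annotation = ann)
  wb <- make_windows(rec)
  expect_equal(dim(wb$inputs), c(2, 352, 2))
  expect_equal(wb$out_starts, c(1L, 177L))
  expect_equal(wb$window_starts, c(1L, 177L) - 88L)
  expect_equal(wb$targets[1, 101, 1], 1)
  expect_equal(wb$targets[1, 150, 2], 1)
  expect_equal(sum(wb$targets), 2)
  short <- vent_record("p", rnorm(175), rnorm(175))
  expect_error(make_windows(short), "shorter than output_len")
})

test_that("windows tile any record length with conserved labels", {
  for (n in c(176L, 300L, 352L, 531L)) {
    set.seed(n)
    n_on <- 3L
    insp <- sort(sample(seq(5L, n - 10L, by = 12L), n_on))
    expo <- insp + 5L
    rec <- vent_record("p", rnorm(n), rnorm(n),
                       annotation = onset_annotation(insp, expo))
    wb <- make_windows(rec)
    K <- ceiling(n / 176)
    expect_equal(dim(wb$inputs)[1], K)
    # spans cover [1, K*176] exactly once
    spans <- unlist(lapply(wb$out_starts, function(s) s:(s + 175L)))
    expect_equal(sort(spans), 1:(K * 176L))
    expect_equal(sum(wb$targets), 2 * n_on) # label conservation
  }
})

test_that("unannotated records give inference-only batches", {
  rec <- vent_record("p", rnorm(200), rnorm(200))
  wb <- make_windows(rec)
  expect_null(wb$targets)
})
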