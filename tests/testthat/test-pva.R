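square_record <- function() {
  # two identical square breaths: 30 L/min for 1 s, then -15 L/min for 2 s
  one <- c(rep(30, 50), rep(-15, 100))
  flow <- c(rep(-1, 10), one, one, rep(-1, 10))
  insp <- c(11L, 161L)
  expo <- c(61L, 211L)
  vent_record("sq", rep(10, length(flow)), flow,
              annotation = onset_annotation(insp, expo))
}

test_that("breath_table integrates square breaths to textbook volumes", {
  bt <- breath_table(square_record())
  expect_equal(nrow(bt), 1L) # last breath has no successor: dropped
  expect_equal(attr(bt, "n_dropped"), 1L)
  expect_equal(bt$ti, 1)
  expect_equal(bt$te, 2)
  # rectangle area 0.5 L/s x 1 s minus the half-sample transition slivers
  expect_equal(bt$tvi, 500, tolerance = 500 * 0.02)
  expect_equal(bt$tve, 500, tolerance = 500 * 0.03)
})

test_that("zero expiratory flow gives zero exhaled volume", {
  flow <- c(rep(-1, 5), rep(30, 50), rep(0, 100), rep(30, 10))
  rec <- vent_record("z", rep(10, length(flow)), flow,
                     annotation = onset_annotation(c(6L, 156L), 56L))
  bt <- breath_table(rec)
  expect_equal(bt$tve, 0)
  expect_equal(bt$ratio, 0)
})

test_that("timing definition of double triggering uses the cohort mean Ti", {
  rows <- data.frame(ti = c(0.9, 0.9, 0.9), te = c(0.40, 0.45, 1.2),
                     tvi = c(400, 400, 400), tve = c(100, 100, 380))
  rows$ratio <- rows$tve / rows$tvi
  f <- classify_dt_def1(rows)
  expect_identical(f, c(TRUE, FALSE, FALSE)) # 0.45 not < 0.45: strict
  expect_error(classify_dt_def1(rows[0, ]), "empty")
  # depends only on timing: invariant to flow rescaling
  rows2 <- rows; rows2$tvi <- rows$tvi * 7; rows2$tve <- rows$tve * 7
  expect_identical(classify_dt_def1(rows2), f)
})

test_that("volume definition of double triggering follows both clauses", {
  rows <- data.frame(te = c(0.2, 0.2, 0.2, 0.31),
                     tvi = c(400, 400, 300, 400),
                     tve = c(80, 160, 90, 80))
  rows$ratio <- rows$tve / rows$tvi
  expect_identical(classify_dt_def2(rows), c(TRUE, FALSE, TRUE, FALSE))
  bad <- rows; bad$tvi[1] <- 0; bad$ratio <- bad$tve / ifelse(bad$tvi > 0, bad$tvi, NA)
  expect_warning(f <- classify_dt_def2(bad), "non-positive TVi")
  expect_true(is.na(f[1]))
})

test_that("stacked classification needs a real expiratory phase", {
  rows <- data.frame(te = c(1.0, 0.3, 2.0), tvi = c(400, 400, 400),
                     tve = c(300, 100, 380))
  rows$ratio <- rows$tve / rows$tvi
  expect_identical(classify_stacked(rows), c(TRUE, FALSE, FALSE))
  # 0.3 exactly is excluded (strict >); ratio 0.95 never flags
})

test_that("definition flags are invariant to time-axis shifts", {
  rec <- synth_cohort(noise_free_sim(n_patients = 1, breaths = 40,
                                     asynchrony = 0.4, seed = 41))[[1]]
  bt <- breath_table(rec)
  ann <- rec$annotation
  shift <- 37L
  rec2 <- vent_record("s", c(rep(10, shift), rec$pressure),
                      c(rep(-0.5, shift), rec$flow),
                      annotation = onset_annotation(ann$insp_onsets + shift,
                                                    ann$exp_onsets + shift,
                                                    ann$breath_types))
  bt2 <- breath_table(rec2)
  expect_identical(classify_dt_def2(bt), classify_dt_def2(bt2))
  expect_identical(classify_stacked(bt), classify_stacked(bt2))
})

test_that("chi-squared frequency comparison matches the Pearson statistic", {
  mk_report <- function(count, n, cat = "dt_def1") {
    r <- list(n_breaths = n, dt_def1 = 0, dt_def2 = 0, stacked = 0)
    r[[cat]] <- count
    structure(c(r, list(source = "x")), class = "pva_report")
  }
  # identical frequencies: statistic 0, p = 1
  same <- suppressWarnings(compare_frequencies(mk_report(30, 100), mk_report(30, 100)))
  expect_equal(same$statistic[1], 0, tolerance = 1e-12)
  expect_equal(same$p_value[1], 1)

  # [[30,70],[10,90]]: expected 20/80 per margin, X2 = 2*(100/20 + 100/80)
  cmp <- suppressWarnings(compare_frequencies(mk_report(30, 100), mk_report(10, 100)))
  expect_equal(cmp$statistic[1], 12.5, tolerance = 1e-9)
  oracle <- stats::chisq.test(matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
                              correct = FALSE)
  expect_equal(cmp$statistic[1], unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(cmp$p_value[1], oracle$p.value, tolerance = 1e-9)

  # homogeneity of degree 1: doubling all cells doubles the statistic
  dbl <- suppressWarnings(compare_frequencies(mk_report(60, 200), mk_report(20, 200)))
  expect_equal(dbl$statistic[1], 2 * cmp$statistic[1], tolerance = 1e-9)

  # zero margin: no events anywhere (one warning per category)
  w <- capture_warnings(z <- compare_frequencies(mk_report(0, 100), mk_report(0, 100)))
  expect_true(all(grepl("zero margin", w)))
  expect_equal(z$p_value, rep(1, 3))
  expect_equal(z$statistic, rep(0, 3))
})

test_that("planted breath types are recovered from ground-truth onsets", {
  rec <- synth_cohort(noise_free_sim(n_patients = 1, breaths = 120,
                                     asynchrony = 0.35, seed = 47))[[1]]
  bt <- breath_table(rec)
  pred <- ifelse(classify_dt_def2(bt), "double_trigger",
                 ifelse(classify_stacked(bt), "stacked", "normal"))
  expect_gte(mean(pred == bt$btype), 0.98)
})
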