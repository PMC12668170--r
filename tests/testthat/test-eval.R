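test_that("event matching is one-to-one with earlier-reference tie-break", {
  m <- match_events(100L, 103L, 5)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))

  m2 <- match_events(100L, c(100L, 103L), 5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  expect_equal(m2$matches$pred, 100L) # smaller offset wins

  m3 <- match_events(c(100L, 104L), 102L, 5)
  expect_equal(c(m3$tp, m3$fn), c(1L, 1L))
  expect_equal(m3$matches$ref, 100L) # |2| both ways: earlier reference wins

  m4 <- match_events(c(10L, 20L), c(30L, 40L), 5)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0L, 2L, 2L))
  expect_equal(match_events(integer(0), 5L, 0)$fp, 1L)
})

test_that("swapping reference and predicted swaps fp and fn", {
  set.seed(4)
  for (i in 1:20) {
    a <- sort(sample(1:200, 6))
    b <- sort(sample(1:200, 4))
    m <- match_events(a, b, 5)
    s <- match_events(b, a, 5)
    expect_equal(m$tp, s$tp)
    expect_equal(m$fp, s$fn)
    expect_equal(m$fn, s$fp)
  }
})

test_that("prf1 computes the harmonic mean and warns on empty denominators", {
  expect_equal(prf1(list(tp = 1, fp = 1, fn = 0)),
               c(precision = 0.5, recall = 1, f1 = 2 / 3))
  expect_equal(prf1(list(tp = 99, fp = 1, fn = 1)),
               c(precision = 0.99, recall = 0.99, f1 = 0.99))
  expect_warning(z <- prf1(list(tp = 0, fp = 0, fn = 0)), "empty denominator")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("matched counts are monotone in the tolerance", {
  set.seed(11)
  for (i in 1:20) {
    ref <- sort(sample(1:500, 8))
    pred <- sort(unique(ref + sample(-8:8, 8, replace = TRUE)))
    tps <- vapply(c(0, 2, 5, 10), function(tol) match_events(ref, pred, tol)$tp,
                  numeric(1))
    expect_true(all(diff(tps) >= 0))
  }
})

test_that("greedy matching equals the exhaustive assignment oracle for separated events", {
  # reference events separated by more than twice the tolerance, as breath
  # onsets are at 50 Hz with a 0.1 s window: the compatibility graph is a
  # union of stars and greedy matching attains the optimum
  set.seed(21)
  for (i in 1:50) {
    n_ref <- sample(1:6, 1)
    ref <- cumsum(sample(12:40, n_ref, replace = TRUE))
    keep <- stats::runif(n_ref) < 0.8
    pred <- ref[keep] + sample(-6:6, sum(keep), replace = TRUE)
    pred <- sort(unique(c(pred, sample(1:max(ref + 10), sample(0:2, 1)))))
    g <- match_events(ref, pred, 5)
    o <- match_events(ref, pred, 5, method = "optimal")
    expect_equal(g$tp, o$tp)
    expect_equal(sum(abs(g$matches$offset)), sum(abs(o$matches$offset)))
  }
})

test_that("greedy never exceeds the optimal assignment on dense instances", {
  set.seed(33)
  for (i in 1:30) {
    ref <- sort(sample(1:30, sample(2:6, 1)))
    pred <- sort(sample(1:30, sample(2:6, 1)))
    g <- match_events(ref, pred, 3)
    o <- match_events(ref, pred, 3, method = "optimal")
    expect_lte(g$tp, o$tp)
  }
})

test_that("stratified metrics partition the pooled counts", {
  rec <- synth_cohort(noise_free_sim(n_patients = 1, breaths = 60,
                                     asynchrony = 0.3, seed = 13))[[1]]
  ann <- rec$annotation
  pred <- zero_crossing_segment(rec)
  tab <- stratified_eval(ann, pred, 5)
  pooled <- tab[tab$stratum == "all", ]
  strat <- tab[tab$stratum != "all", ]
  for (ot in c("insp", "exp")) {
    expect_equal(sum(strat$tp[strat$onset_type == ot]),
                 pooled$tp[pooled$onset_type == ot])
  }
  # perfect predictions on every stratum here
  expect_true(all(tab$recall == 1))

  # stratified output degrades per stratum when one class is unserved
  pva_first <- ann$insp_onsets[ann$breath_types != "normal"]
  norm_only <- list(insp_onsets = setdiff(ann$insp_onsets, pva_first),
                    exp_onsets = integer(0))
  tab2 <- stratified_eval(ann, norm_only, 5)
  expect_equal(tab2$recall[tab2$stratum == "pva" & tab2$onset_type == "insp"], 0)
  expect_equal(tab2$recall[tab2$stratum == "normal" & tab2$onset_type == "insp"], 1)

  no_types <- onset_annotation(ann$insp_onsets, ann$exp_onsets)
  expect_error(stratified_eval(no_types, pred, 5), "breath_types")
})

test_that("sample-size formula reproduces the printed requirement", {
  expect_identical(required_sample_size(0.70, 0.80, 0.80, 0.05), 291L)
  expect_identical(required_sample_size(0.70, 0.80, 0.80, 0.05,
                                        variant = "pooled"), 294L)
  # brute-force power inversion oracle for a different power
  power_of <- function(n, p0, p1, alpha) {
    se <- sqrt(p0 * (1 - p0) + p1 * (1 - p1))
    stats::pnorm(sqrt(n) * abs(p1 - p0) / se - stats::qnorm(1 - alpha / 2))
  }
  oracle <- which(vapply(1:2000, power_of, numeric(1),
                         p0 = 0.70, p1 = 0.80, alpha = 0.05) >= 0.90)[1]
  expect_identical(required_sample_size(0.70, 0.80, 0.90, 0.05), oracle)
  # requirement diverges as the detectable difference shrinks
  ns <- vapply(c(0.05, 0.02, 0.01, 0.005), function(d)
    required_sample_size(0.5, 0.5 + d, 0.80, 0.05), integer(1))
  expect_true(all(diff(ns) > 0))
  expect_error(required_sample_size(0.5, 0.5), "differ")
})
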