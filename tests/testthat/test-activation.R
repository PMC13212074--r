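test_that("epoch segmentation applies the extraction and baseline rules", {
  hb <- make_hb(matrix(0, 2970, 48))
  eps <- segment_epochs(hb)
  expect_equal(eps$freeze_induction$task, c(63, 120))
  expect_equal(eps$freeze_induction$baseline, c(55, 60))
  expect_equal(eps$normal_walk$task, c(153, 210))
  expect_equal(eps$normal_walk$baseline, c(145, 150))
  expect_equal(eps$rest$task, c(0, 60))
  expect_null(eps$rest$baseline)
  # sample counts from the half-open convention
  expect_length(eps$freeze_induction$task_idx, 627L)
  expect_length(eps$freeze_induction$baseline_idx, 55L)
  expect_length(eps$normal_walk$task_idx, 627L)
})

test_that("a paradigm with a missing condition is rejected by name", {
  p <- default_paradigm()
  p$analysis_windows$rest <- NULL
  hb <- make_hb(matrix(0, 2970, 48))
  expect_error(segment_epochs(hb, p), "rest")
})

test_that("recordings too short for the windows are rejected", {
  hb <- make_hb(matrix(0, 1000, 48))
  expect_error(segment_epochs(hb), "outside")
})

test_that("block averaging is the samplewise mean with strict shape checks", {
  x <- stats::rnorm(50)
  expect_identical(block_average(list(x)), x)
  expect_equal(block_average(list(x, x)), x)
  y <- stats::rnorm(50)
  expect_equal(block_average(list(x, y)), (x + y) / 2)
  expect_error(block_average(list(x, y[-1])), "mismatch")
})

test_that("block averaging halves noise variance in expectation", {
  set.seed(61)
  v1 <- replicate(100, stats::var(block_average(list(stats::rnorm(200)))))
  v2 <- replicate(100, stats::var(block_average(
    list(stats::rnorm(200), stats::rnorm(200)))))
  expect_equal(mean(v2) / mean(v1), 0.5, tolerance = 0.1)
})

test_that("activation is the baseline-corrected task mean", {
  n <- 2970; fs <- 11
  # constant series: zero activation
  hb0 <- make_hb(matrix(4, n, 48))
  expect_equal(max(abs(activation_value(hb0, "freeze_induction"))), 0)
  # clean unit step at the walk onset: activation exactly 1
  step <- matrix(rep(as.numeric((0:(n - 1)) / fs >= 60), 48), n, 48)
  hb1 <- make_hb(step)
  expect_equal(unname(activation_value(hb1, "freeze_induction")),
               rep(1, 48))
  # invariant to adding any constant; linear in amplitude
  set.seed(62)
  x <- matrix(stats::rnorm(n * 48), n, 48)
  a0 <- activation_value(make_hb(x), "freeze_induction")
  expect_equal(activation_value(make_hb(x + 17.3), "freeze_induction"), a0,
               tolerance = 1e-9)
  expect_equal(activation_value(make_hb(3 * x), "freeze_induction"), 3 * a0,
               tolerance = 1e-9)
})

test_that("ROI aggregation is the unweighted mean over retained channels", {
  m <- build_default_montage()
  vals <- stats::setNames(rep(2.5, 48), 1:48)
  expect_true(all(roi_aggregate(vals, m) == 2.5))
  vals2 <- stats::setNames(stats::rnorm(48), 1:48)
  agg <- roi_aggregate(vals2, m)
  expect_equal(unname(agg["M1"]), mean(vals2[c("37", "44")]))
  expect_equal(unname(agg["PFC"]),
               mean(vals2[as.character(m$roi_map$PFC)]))
  # QC-dropped channel is omitted, not zeroed
  vals3 <- vals2
  vals3["37"] <- NA
  expect_equal(unname(roi_aggregate(vals3, m)["M1"]),
               unname(vals2["44"]))
  # an ROI with no retained channels yields NA with a warning
  vals4 <- vals2
  vals4[c("37", "44")] <- NA
  expect_warning(agg4 <- roi_aggregate(vals4, m), "M1")
  expect_true(is.na(agg4["M1"]))
})
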