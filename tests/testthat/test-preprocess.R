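test_that("channel CV quality control follows the strict exclusion rule", {
  # hand-checkable two-sample series: CV of (100, 120) = 100*sd/mean = 12.86
  n <- 100
  base <- array(1000, dim = c(n, 3, 2))
  base[, 2, ] <- rep(c(100, 120), length.out = n)   # cv ~ 9.1% over n=100...
  rec <- structure(list(data = base, fs = 11, subject_id = "q", group = "HC",
                        wavelengths = c(730, 850)),
                   class = "fnirs_recording")
  two <- structure(list(data = array(rep(c(100, 120), 2 * 2),
                                     dim = c(2, 2, 2)),
                        fs = 11, subject_id = "q", group = "HC",
                        wavelengths = c(730, 850)),
                   class = "fnirs_recording")
  qc2 <- channel_qc(two)
  expect_equal(qc2$cv_730[1], 100 * stats::sd(c(100, 120)) / 110,
               tolerance = 1e-12)
  expect_equal(qc2$cv_730[1], 12.856, tolerance = 1e-3)
  expect_true(all(qc2$retained))
  # constant channel: cv = 0, retained
  qc <- channel_qc(rec)
  expect_equal(qc$cv_730[1], 0)
  expect_true(qc$retained[1])
  # exclusion is strictly 'CV > threshold': a channel at exactly the
  # threshold stays in
  cv_exact <- qc2$cv_730[1]
  expect_true(all(channel_qc(two, threshold = cv_exact)$retained))
  expect_false(any(channel_qc(two, threshold = cv_exact - 1e-9)$retained))
})

test_that("channels with non-positive mean intensity are excluded with a reason", {
  d <- array(1000, dim = c(10, 2, 2))
  d[, 2, 1] <- 0
  rec <- structure(list(data = d, fs = 11, subject_id = "q", group = "HC",
                        wavelengths = c(730, 850)),
                   class = "fnirs_recording")
  qc <- channel_qc(rec)
  expect_false(qc$retained[2])
  expect_equal(qc$reason[2], "undefined_cv")
})

test_that("optical density conversion satisfies the log10 identities", {
  n <- 50
  d <- array(500, dim = c(n, 2, 2))
  rec <- structure(list(data = d, fs = 11, subject_id = "q", group = "HC",
                        wavelengths = c(730, 850)),
                   class = "fnirs_recording")
  od <- intensity_to_od(rec)
  expect_equal(max(abs(od)), 0)   # I == mean -> dOD = 0
  # a tenfold intensity drop at one sample gives dOD ~ 1 there
  d2 <- d
  d2[25, 1, 1] <- mean(d2[, 1, 1]) / 10
  rec2 <- structure(list(data = d2, fs = 11, subject_id = "q", group = "HC",
                         wavelengths = c(730, 850)),
                    class = "fnirs_recording")
  od2 <- intensity_to_od(rec2)
  ref <- -log10((500 / 10) / mean(d2[, 1, 1]))
  expect_equal(od2[25, 1, 1], ref, tolerance = 1e-12)
  set.seed(31)
  d3 <- array(exp(stats::rnorm(n * 4, 6, 0.02)), dim = c(n, 2, 2))
  rec3 <- structure(list(data = d3, fs = 11, subject_id = "q", group = "HC",
                         wavelengths = c(730, 850)),
                    class = "fnirs_recording")
  od3 <- intensity_to_od(rec3)
  # mean dOD is the (small) Jensen offset between log of mean and mean of log
  expect_lt(abs(mean(od3[, 1, 1])), 5e-4)
})

test_that("motion detection flags spikes and nothing on clean input", {
  fs <- 11
  clean <- matrix(smooth_od(seed = 41), ncol = 1)
  expect_equal(sum(detect_motion_artifacts(clean, fs)), 0L)
  inj <- inject_artifact(clean[, 1], "spike", t = 120,
                         magnitude = 10 * stats::sd(clean), fs = fs)
  m <- detect_motion_artifacts(matrix(inj$series, ncol = 1), fs)
  expect_true(any(m[inj$mask, 1]))
  # the flagged run is contiguous and covers the spike +/- t_mask
  runs <- rle(m[, 1])
  expect_equal(sum(runs$values), 1L)
  flagged_s <- range(which(m[, 1])) / fs
  expect_lte(flagged_s[1], 120 - 0.4)
  expect_gte(flagged_s[2], 120 + 0.4)
  # effectively infinite thresholds flag nothing, whatever the input
  loose <- motion_params(stdev_thresh = 1e12, amp_thresh = 1e12)
  expect_equal(sum(detect_motion_artifacts(matrix(inj$series, ncol = 1),
                                           fs, loose)), 0L)
})

test_that("spline correction removes baseline steps and is idempotent", {
  fs <- 11
  od <- matrix(smooth_od(seed = 42), ncol = 1)
  # empty mask: identity
  expect_identical(spline_correct(od, matrix(FALSE, nrow(od), 1), fs), od)
  inj <- inject_artifact(od[, 1], "shift", t = 100, magnitude = 5, fs = fs)
  m <- detect_motion_artifacts(matrix(inj$series, ncol = 1), fs)
  expect_true(any(m))
  corr <- spline_correct(matrix(inj$series, ncol = 1), m, fs)
  seg <- which(m[, 1])
  pre <- (min(seg) - round(fs)):(min(seg) - 1)
  # between-segment mean difference < 5% of the step height
  expect_lt(abs(mean(corr[seg, 1]) - mean(corr[pre, 1])) / 5, 0.05)
  # the sustained step after the mask is levelled out as well
  post <- (max(seg) + 1):(max(seg) + 5 * fs)
  expect_lt(abs(mean(corr[post, 1]) - mean(corr[pre, 1])) / 5, 0.05)
  # re-detection on the corrected series finds nothing
  expect_equal(sum(detect_motion_artifacts(corr, fs)), 0L)
})

test_that("preprocessing is deterministic and channel-order equivariant", {
  spec <- cohort_spec(seed = 1)
  rec <- simulate_session(spec, "p1", "HC", seed = 5)
  hb1 <- preprocess(rec)
  hb2 <- preprocess(rec)
  expect_identical(hb1$data, hb2$data)
  # permuting channels permutes every per-channel output
  perm <- sample(seq_len(dim(rec$data)[2]))
  rec_p <- rec
  rec_p$data <- rec$data[, perm, , drop = FALSE]
  hb_p <- preprocess(rec_p)
  expect_equal(hb_p$data[, , "HbO2"], hb1$data[, perm, "HbO2"],
               tolerance = 1e-10)
  expect_equal(hb_p$qc$retained, hb1$qc$retained[perm])
})

test_that("QC-excluded channels carry no finite values downstream", {
  spec <- cohort_spec(seed = 1)
  rec <- simulate_session(spec, "p2", "HC", seed = 6)
  # wreck one channel's signal quality
  n <- dim(rec$data)[1]
  rec$data[, 7, ] <- rec$data[, 7, ] *
    exp(stats::rnorm(n, sd = 0.4))
  hb <- preprocess(rec)
  expect_false(hb$qc$retained[7])
  expect_true(all(is.na(hb$data[, 7, ])))
  av <- activation_value(hb, "freeze_induction")
  expect_true(is.na(av[7]))
  expect_true(all(is.finite(av[-7])))
})
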