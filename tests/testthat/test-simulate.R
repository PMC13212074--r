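test_that("the HRF peaks 4-7 s after neural onset", {
  k <- hrf_kernel(hrf_spec(), fs = 11)
  t_peak <- (which.max(k) - 1) / 11
  expect_gt(t_peak, 4)
  expect_lt(t_peak, 7)
  expect_equal(t_peak, 5.5, tolerance = 0.2)
  expect_equal(max(k), 1)
  # response is delayed: essentially nothing before the onset delay
  expect_lt(max(abs(k[seq_len(floor(1.5 * 11))])), 0.02)
})

test_that("identical seeds give bit-identical sessions", {
  spec <- cohort_spec(seed = 1)
  r1 <- simulate_session(spec, "a", "PD_FOG", seed = 12345)
  r2 <- simulate_session(spec, "a", "PD_FOG", seed = 12345)
  expect_identical(r1$data, r2$data)
  expect_identical(attr(r1, "ground_truth")$beta,
                   attr(r2, "ground_truth")$beta)
  r3 <- simulate_session(spec, "a", "PD_FOG", seed = 12346)
  expect_false(identical(r1$data, r3$data))
})

test_that("the null generator emits constant intensity per channel", {
  ae0 <- default_activation_effects()
  ae0$mean <- 0
  spec <- cohort_spec(activation_effects = ae0)
  rec <- simulate_session(spec, "z", "HC", seed = 1, noise_free = TRUE)
  ranges <- apply(rec$data[, , 1], 2, function(x) diff(range(x)))
  expect_equal(max(ranges), 0)
})

test_that("noise-free sessions round-trip the nominal activation effects", {
  ae <- default_activation_effects()
  ae$mean[ae$roi == "M1" & ae$condition == "freeze_induction" &
            ae$group == "HC"] <- 0.04
  spec <- cohort_spec(activation_effects = ae)
  rec <- simulate_session(spec, "nf", "HC", seed = 1, noise_free = TRUE)
  hb <- preprocess(rec)
  a <- roi_aggregate(activation_value(hb, "freeze_induction"))
  expect_equal(unname(a["M1"]), 0.04, tolerance = 1e-6)
  # full chain recovers every injected amplitude in both walking windows
  an <- roi_aggregate(activation_value(hb, "normal_walk"))
  for (r in montage_rois()) {
    tgt_f <- ae$mean[ae$roi == r & ae$condition == "freeze_induction" &
                       ae$group == "HC"]
    tgt_n <- ae$mean[ae$roi == r & ae$condition == "normal_walk" &
                       ae$group == "HC"]
    expect_equal(unname(a[r]), tgt_f, tolerance = 1e-6)
    expect_equal(unname(an[r]), tgt_n, tolerance = 1e-6)
  }
})

test_that("generated correlations converge to the latent structure", {
  # two blocks sharing latent signal at rho = 0.4 / 0.0, long series
  set.seed(51)
  n <- 10 * 2970
  C <- diag(12)
  C[1:6, 1:6] <- 0.4
  diag(C) <- 1
  x <- fognirs:::.fluct_field(n, 12, C, 0.1, 11)
  r <- stats::cor(x)
  blk <- r[1:6, 1:6][upper.tri(r[1:6, 1:6])]
  expect_lt(abs(mean(blk) - 0.4), 0.05)
  expect_lt(abs(mean(r[7:12, 1:6])), 0.05)
  expect_lt(max(abs(blk - 0.4)), 0.12)
  expect_lt(max(abs(r[7:12, 1:6])), 0.12)
})

test_that("artifact injection matches its documented shapes and masks", {
  x <- rep(0, 2970)
  same <- inject_artifact(x, "spike", t = 50, magnitude = 0, fs = 11)
  expect_identical(same$series, x)
  expect_false(any(same$mask))
  sp <- inject_artifact(x, "spike", t = 50, magnitude = 2, fs = 11)
  expect_equal(max(sp$series), 2, tolerance = 1e-6)
  expect_lte(diff(range(which(sp$series != 0))) / 11, 1.0)  # transient <= 1 s
  sh <- inject_artifact(x, "shift", t = 100, magnitude = 3, fs = 11)
  expect_equal(sh$series[2970], 3)
  expect_equal(sh$series[1], 0)
  # ground-truth mask spans [99, 101] s around the step
  ms <- range(which(sh$mask)) / 11
  expect_equal(ms[1], 99, tolerance = 0.2)
  expect_equal(ms[2], 101, tolerance = 0.2)
  expect_error(inject_artifact(x, "spike", t = 400, magnitude = 1, fs = 11),
               "outside")
})

test_that("cohort generation is a pure function of spec and seed", {
  spec <- cohort_spec(n_per_group = 2, seed = 77)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_length(c1$recordings, 4L)
  expect_equal(vapply(c1$recordings, function(r) r$group, ""),
               rep(c("HC", "PD_FOG"), each = 2))
  expect_identical(c1$recordings[[3]]$data, c2$recordings[[3]]$data)
  expect_identical(c1$gait, c2$gait)
})

test_that("gait tables encode the freezing deficit and intervention effects", {
  spec <- cohort_spec(seed = 5)
  set.seed(5)
  gait <- simulate_gait(spec, sprintf("P%02d", 1:28), rep("PD_FOG", 28))
  fr <- gait[gait$condition == "freeze_induction" & gait$intervention == "NONE", ]
  nw <- gait[gait$condition == "normal_walk", ]
  expect_equal(nrow(fr), 28L)
  # freezing: slower, shorter strides, wider sway
  expect_lt(mean(fr$velocity), mean(nw$velocity))
  expect_lt(mean(fr$stride_length), mean(nw$stride_length))
  expect_gt(mean(fr$swing_width), mean(nw$swing_width))
  expect_true(all(gait$fog_count >= 0 & gait$fog_count == round(gait$fog_count)))
  expect_true(all(gait[, c("cadence", "stride_length", "velocity")] >= 0))
  rb <- gait[gait$intervention == "RAS_B", ]
  expect_lt(mean(rb$fog_count), mean(fr$fog_count))
})

test_that("infeasible connectivity targets raise an explicit error", {
  fc <- default_fc_structure()
  # strongly inconsistent: near-perfect coupling everywhere but one
  # strongly negative pair cannot be a valid correlation structure
  fc$mean[fc$roi_a != fc$roi_b] <- 0.9
  fc$mean[fc$roi_a == "S1" & fc$roi_b == "TLC"] <- -0.9
  fc$mean[fc$roi_a == "NONE" | fc$roi_b == "NONE"] <- 0.01
  spec <- cohort_spec(fc_structure = fc)
  expect_error(simulate_session(spec, "x", "HC", seed = 1),
               "infeasible correlation structure")
})
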