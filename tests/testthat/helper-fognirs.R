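# Shared fixtures, all built in code.

# short paradigm for I/O tests (9 s instead of 270 s)
tiny_paradigm <- function() {
  p <- structure(
    list(
      blocks = data.frame(
        label = c("stand", "freeze_walk", "rest", "normal_walk", "stand"),
        start = c(0, 2, 4, 5, 7), end = c(2, 4, 5, 7, 9)),
      analysis_windows = list(rest = c(0, 2), freeze_induction = c(2.5, 4),
                              normal_walk = c(5.5, 7)),
      walk_onsets = c(freeze_induction = 2, normal_walk = 5),
      baseline_window_s = 1, task_extract_window = c(0.5, 2)
    ),
    class = "fnirs_paradigm")
  validate_paradigm(p)
}

tiny_recording <- function(n_ch = 4, fs = 11, seed = 1) {
  set.seed(seed)
  n <- ceiling(9 * fs)
  data <- array(exp(stats::rnorm(n * n_ch * 2, mean = 6, sd = 0.05)),
                dim = c(n, n_ch, 2))
  new_recording(data, fs = fs, subject_id = "T01", group = "HC",
                paradigm = tiny_paradigm())
}

# hemoglobin-series container around a given HbO2 matrix (time x channel)
make_hb <- function(hbo, fs = 11, paradigm = default_paradigm()) {
  n <- nrow(hbo); nch <- ncol(hbo)
  arr <- array(c(hbo, -hbo / 3), dim = c(n, nch, 2),
               dimnames = list(NULL, NULL, c("HbO2", "HHb")))
  structure(
    list(data = arr, fs = fs, subject_id = "T01", group = "HC",
         paradigm = paradigm,
         qc = data.frame(channel = seq_len(nch), retained = TRUE),
         artifact_mask = matrix(FALSE, n, nch)),
    class = "hb_series")
}

# smooth + white test series resembling optical-density traces
smooth_od <- function(n = 2970, fs = 11, sd_slow = 0.01, sd_white = 8e-4,
                      seed = 1) {
  set.seed(seed)
  slow <- bandpass(stats::rnorm(n), fs)
  slow <- sd_slow * slow / stats::sd(slow)
  slow + stats::rnorm(n, sd = sd_white)
}

# Full-cohort contrasts for the paper-like / null presets: freeze-window
# ROI activation, ROI-pair connectivity and channel-level activation for
# every subject. Used by the acceptance checks.
cohort_contrasts <- function(spec, cohort_seed, fs = 11,
                             montage = build_default_montage()) {
  set.seed(cohort_seed)
  n <- spec$n_per_group
  groups <- rep(c("HC", "PD_FOG"), each = n)
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
  act <- matrix(NA_real_, 2 * n, 5)
  fcv <- matrix(NA_real_, 2 * n, 15)
  chact <- matrix(NA_real_, 2 * n, 48)
  fl <- NULL
  for (i in seq_len(2 * n)) {
    rec <- simulate_session(spec, paste0("s", i), groups[i], seed = seeds[i],
                            fs = fs, montage = montage)
    hb <- preprocess(rec)
    eps <- segment_epochs(hb)
    cv <- activation_value(hb, "freeze_induction", eps)
    chact[i, ] <- cv
    act[i, ] <- suppressWarnings(roi_aggregate(cv, montage))
    pr <- roi_pair_fc(suppressWarnings(fc_matrix(hb, "freeze_induction", eps)),
                      montage)
    fcv[i, ] <- pr$value
    if (is.null(fl)) fl <- paste0(pr$roi_a, "-", pr$roi_b)
  }
  colnames(act) <- montage_rois()
  colnames(fcv) <- fl
  list(act = act, fc = fcv, channel = chact, groups = groups)
}

pooled_d <- function(x, y) {
  (mean(y) - mean(x)) / sqrt((stats::var(x) + stats::var(y)) / 2)
}
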