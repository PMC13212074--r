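# Synthetic cohort generator.
#
# Each simulated session builds, per channel, a hemoglobin concentration
# series as the sum of (i) an evoked component: ROI-specific boxcar neural
# drive during the walking blocks convolved with a double-gamma HRF,
# (ii) a band-limited latent fluctuation field carrying the target
# channel-channel correlation structure, and (iii) physiological noise
# (cardiac, respiratory, Mayer waves, drift, white noise). Concentrations
# are forward-mapped through the same MBLL constants the preprocessing
# inverse uses, artifacts are injected in the optical-density domain, and
# dual-wavelength intensities are emitted.
#
# Calibration: effect targets are stated on the *observed* scale (what the
# analysis pipeline reports for a cohort). The generator therefore
# (a) solves drive amplitudes from a linear response map so the pipeline's
# noise-free activation estimate equals the nominal effect, (b) shrinks
# between-subject draw SDs by the pipeline's measurement variance, and
# (c) scales latent correlations by the in-band noise attenuation factor.

#' Physiological noise specification
#'
#' Amplitudes are concentration-equivalent (micromol/L); oscillation
#' amplitudes are sinusoid amplitudes (variance amp^2/2). Frequencies are
#' jittered slightly per subject. Cardiac (~1 Hz) and respiratory
#' (~0.3 Hz) oscillations lie outside the 0.01--0.2 Hz analysis band;
#' Mayer waves (~0.1 Hz) lie inside it.
#'
#' @param cardiac_freq,cardiac_amp Cardiac oscillation (Hz, umol/L).
#' @param resp_freq,resp_amp Respiratory oscillation.
#' @param mayer_freq,mayer_amp Mayer-wave oscillation.
#' @param drift_slope_sd SD of the per-channel linear drift slope (umol/L/s).
#' @param drift_rw_sd Random-walk innovation SD (umol/L per sqrt(s)).
#' @param white_sd White measurement noise SD (umol/L).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cardiac_freq = 1.0, cardiac_amp = 0.05,
                       resp_freq = 0.3, resp_amp = 0.03,
                       mayer_freq = 0.1, mayer_amp = 0.008,
                       drift_slope_sd = 0.001, drift_rw_sd = 0.01,
                       white_sd = 0.05) {
  amps <- c(cardiac_amp, resp_amp, mayer_amp, drift_slope_sd, drift_rw_sd,
            white_sd)
  stopifnot(all(amps >= 0))
  structure(list(cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
                 resp_freq = resp_freq, resp_amp = resp_amp,
                 mayer_freq = mayer_freq, mayer_amp = mayer_amp,
                 drift_slope_sd = drift_slope_sd, drift_rw_sd = drift_rw_sd,
                 white_sd = white_sd),
            class = "noise_spec")
}

#' Default group activation effects
#'
#' Mean and between-subject SD of the observed task activation
#' (mean task-window minus baseline HbO2 change, micromol/L) per group, ROI
#' and condition. Freezing-induction values follow the group contrast this
#' cohort design is built around: healthy controls activate S1, M1 and PFC
#' during induced freezing while patients do not. Normal-walk values are
#' moderate activations with a smaller group gap.
#'
#' @return data.frame with columns `group`, `condition`, `roi`, `mean`, `sd`.
#' @export
default_activation_effects <- function() {
  rois <- montage_rois()  # PFC PMC M1 S1 TLC
  fr <- rbind(
    data.frame(group = "HC", condition = "freeze_induction", roi = rois,
               mean = c(0.034, 0.025, 0.043, 0.036, 0.000),
               sd   = c(0.045, 0.047, 0.058, 0.060, 0.071)),
    data.frame(group = "PD_FOG", condition = "freeze_induction", roi = rois,
               mean = c(-0.013, 0.009, -0.007, -0.011, 0.021),
               sd   = c(0.075, 0.049, 0.065, 0.067, 0.079)),
    data.frame(group = "HC", condition = "normal_walk", roi = rois,
               mean = c(0.028, 0.022, 0.035, 0.030, 0.005),
               sd   = c(0.045, 0.047, 0.058, 0.060, 0.071)),
    data.frame(group = "PD_FOG", condition = "normal_walk", roi = rois,
               mean = c(0.005, 0.015, 0.012, 0.015, 0.015),
               sd   = c(0.075, 0.049, 0.065, 0.067, 0.079))
  )
  fr
}

#' Default latent functional-connectivity structure
#'
#' Target mean and between-subject SD of the observed ROI-pair Pearson
#' connectivity (freezing-induction window) per group. Patients show
#' elevated connectivity in every reported pair; unreported pairs carry
#' moderate values with the same group ordering. Rows with
#' `roi_a == roi_b` are intra-ROI targets. `NONE` rows set the weak
#' residual coupling of unassigned channels.
#'
#' @return data.frame with columns `group`, `roi_a`, `roi_b`, `mean`, `sd`.
#' @export
default_fc_structure <- function() {
  inter <- data.frame(
    roi_a = c("S1", "S1", "PMC", "M1", "M1", "PFC", "S1", "S1", "PMC", "PMC"),
    roi_b = c("PFC", "TLC", "TLC", "PFC", "TLC", "TLC", "PMC", "M1", "M1", "PFC"),
    hc_mean = c(0.124, 0.047, 0.054, 0.109, 0.024, 0.037, 0.090, 0.110, 0.100, 0.095),
    hc_sd   = c(0.112, 0.124, 0.106, 0.141, 0.150, 0.080, 0.120, 0.130, 0.130, 0.120),
    pd_mean = c(0.239, 0.202, 0.187, 0.240, 0.198, 0.182, 0.210, 0.230, 0.215, 0.220),
    pd_sd   = c(0.171, 0.191, 0.152, 0.195, 0.200, 0.158, 0.170, 0.180, 0.175, 0.170)
  )
  # S1/M1/PMC intra values are not tabulated in the source cohort; their
  # SDs reflect the pair counts (intra-M1 is a single channel pair, so its
  # subject-level value is intrinsically noisy)
  intra <- data.frame(
    roi_a = c("PFC", "TLC", "S1", "M1", "PMC"),
    roi_b = c("PFC", "TLC", "S1", "M1", "PMC"),
    hc_mean = c(0.145, 0.133, 0.150, 0.150, 0.150),
    hc_sd   = c(0.112, 0.125, 0.160, 0.250, 0.130),
    pd_mean = c(0.274, 0.292, 0.290, 0.290, 0.280),
    pd_sd   = c(0.186, 0.179, 0.190, 0.280, 0.180)
  )
  # unassigned channels: weak residual coupling among themselves and to
  # the labelled regions
  none <- data.frame(
    roi_a = c("NONE", rep("NONE", 5)),
    roi_b = c("NONE", montage_rois()),
    hc_mean = c(0.05, rep(0.01, 5)), hc_sd = 0.03,
    pd_mean = c(0.05, rep(0.01, 5)), pd_sd = 0.03
  )
  tab <- rbind(inter, intra, none)
  long <- rbind(
    data.frame(group = "HC", roi_a = tab$roi_a, roi_b = tab$roi_b,
               mean = tab$hc_mean, sd = tab$hc_sd),
    data.frame(group = "PD_FOG", roi_a = tab$roi_a, roi_b = tab$roi_b,
               mean = tab$pd_mean, sd = tab$pd_sd)
  )
  long
}

#' Default gait-parameter effects
#'
#' Distributional targets for the simulated gait tables: patients during
#' induced freezing walk slower with shorter strides and wider mediolateral
#' sway than during normal walking; external cueing (RAS-B, RAS-M) improves
#' freezing-period gait more than imagined cueing (RAS-I). `fog_rate` is
#' the Poisson rate of freezing episodes per freezing-induction bout.
#'
#' @return data.frame of means/SDs per group, condition, intervention and
#'   parameter.
#' @export
default_gait_effects <- function() {
  params <- c("cadence", "stride_length", "velocity", "swing_width",
              "foot_progression_angle")
  row <- function(group, condition, intervention, means, sds, fog_rate) {
    data.frame(group = group, condition = condition,
               intervention = intervention, parameter = c(params, "fog_count"),
               mean = c(means, fog_rate), sd = c(sds, NA))
  }
  sds_pd <- c(10, 0.15, 0.18, 2.5, 3.0)
  rbind(
    row("PD_FOG", "freeze_induction", "NONE",  c(92, 0.75, 0.60, 12.0, 7.0), sds_pd, 3.0),
    row("PD_FOG", "freeze_induction", "RAS_B", c(98, 0.85, 0.70, 10.8, 6.5), sds_pd, 1.5),
    row("PD_FOG", "freeze_induction", "RAS_M", c(97, 0.84, 0.69, 10.9, 6.5), sds_pd, 1.6),
    row("PD_FOG", "freeze_induction", "RAS_I", c(93, 0.78, 0.62, 11.7, 6.9), sds_pd, 2.6),
    row("PD_FOG", "normal_walk", "NONE", c(105, 1.00, 0.90, 9.0, 5.0), sds_pd, 0.0),
    row("HC", "normal_walk", "NONE", c(110, 1.15, 1.05, 8.0, 4.0),
        c(9, 0.12, 0.15, 1.8, 2.5), 0.0)
  )
}

#' Cohort simulation specification
#'
#' @param n_per_group Subjects per group (healthy controls and PD with
#'   freezing of gait). Default 28.
#' @param seed Master seed; cohort generation is a pure function of the
#'   spec including this seed.
#' @param hrf An [hrf_spec()].
#' @param noise A [noise_spec()].
#' @param activation_effects Observed-scale activation targets, see
#'   [default_activation_effects()].
#' @param fc_structure Observed-scale connectivity targets, see
#'   [default_fc_structure()].
#' @param fc_amplitude SD (umol/L) of the band-limited latent fluctuation
#'   field that carries the connectivity structure.
#' @param artifact_rate Motion-artifact events per minute.
#' @param artifact_channel_frac Fraction of channels affected by each event
#'   (optode-local motion).
#' @param gait_effects Gait distribution targets, see
#'   [default_gait_effects()].
#' @param gait_subject_re Fraction of gait-parameter variance attributable
#'   to a stable subject effect (drives the pairing across conditions).
#' @param preset `"paper_like"` uses the targets as given; `"null"` erases
#'   every group contrast (patient rows copy the control targets) for
#'   calibration studies.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 28, seed = 1,
                        hrf = hrf_spec(), noise = noise_spec(),
                        activation_effects = default_activation_effects(),
                        fc_structure = default_fc_structure(),
                        fc_amplitude = 0.13,
                        artifact_rate = 0.5, artifact_channel_frac = 0.3,
                        gait_effects = default_gait_effects(),
                        gait_subject_re = 0.6,
                        preset = c("paper_like", "null")) {
  preset <- match.arg(preset)
  stopifnot(n_per_group >= 2, fc_amplitude > 0, artifact_rate >= 0,
            all(stats::na.omit(c(activation_effects$sd, fc_structure$sd)) > 0),
            all(abs(fc_structure$mean) < 1))
  if (preset == "null") {
    for (tab in c("activation_effects", "fc_structure")) {
      x <- get(tab)
      hc <- x[x$group == "HC", ]
      pd <- hc
      pd$group <- "PD_FOG"
      assign(tab, rbind(hc, pd))
    }
  }
  structure(list(n_per_group = as.integer(n_per_group), seed = seed,
                 hrf = hrf, noise = noise,
                 activation_effects = activation_effects,
                 fc_structure = fc_structure, fc_amplitude = fc_amplitude,
                 artifact_rate = artifact_rate,
                 artifact_channel_frac = artifact_channel_frac,
                 gait_effects = gait_effects,
                 gait_subject_re = gait_subject_re,
                 preset = preset),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("fNIRS cohort spec (", x$preset, "): ", x$n_per_group,
      " per group, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.sim_cache <- new.env(parent = emptyenv())

# Linear response map of the default analysis chain: columns are unit
# freeze / normal drives, rows the freeze / normal activation estimates
# after HRF convolution and bandpass filtering. Used to solve drive
# amplitudes so that pipeline estimates equal nominal effects. Also
# caches the filtered unit responses and the per-condition window
# indices for the evoked-contamination calibration below.
.drive_response <- function(fs, paradigm, hrf, fparams = filter_params()) {
  key <- paste("resp", fs, paradigm_duration(paradigm),
               hrf$onset_delay, hrf$time_to_peak, hrf$undershoot_ratio,
               fparams$band[1], fparams$band[2], fparams$order, sep = "_")
  out <- .sim_cache[[key]]
  if (!is.null(out)) return(out)
  n <- floor(paradigm_duration(paradigm) * fs)
  kern <- hrf_kernel(hrf, fs)
  blocks <- paradigm$blocks
  mk_drive <- function(label) {
    d <- numeric(n)
    for (i in which(blocks$label == label)) {
      idx <- window_samples(c(blocks$start[i], blocks$end[i]), fs, n)
      d[idx] <- 1
    }
    d
  }
  u <- cbind(freeze = convolve_drive(mk_drive("freeze_walk"), kern),
             normal = convolve_drive(mk_drive("normal_walk"), kern))
  uf <- bandpass(u, fs, fparams)
  win <- .epoch_windows(paradigm)
  idx <- lapply(win[c("freeze_induction", "normal_walk")], function(w)
    list(task = window_samples(w$task, fs, n),
         baseline = window_samples(w$baseline, fs, n)))
  est <- function(col, cond)
    mean(col[idx[[cond]]$task]) - mean(col[idx[[cond]]$baseline])
  M <- matrix(c(est(uf[, 1], "freeze_induction"), est(uf[, 1], "normal_walk"),
                est(uf[, 2], "freeze_induction"), est(uf[, 2], "normal_walk")),
              2, 2)
  out <- list(shapes = u, filtered = uf, response = M, windows = idx, n = n)
  .sim_cache[[key]] <- out
  out
}

# Empirical calibration of the pipeline's effective variances, run once
# per noise configuration (pinned internal seed; caller's RNG preserved).
# Pushes noise-only sessions (zero evoked drive, identity latent
# correlation) through the full analysis chain and measures, per channel:
#  - the within-window variance of the analysed HbO2 series, split into
#    the latent-fluctuation part and the independent-noise part (white
#    noise, physiological lines, residual drift, artifact-correction
#    residue);
#  - the variance of the activation estimate (task minus baseline means),
#    split the same way.
# These effective values absorb everything the analytic spectra miss
# (finite-window variance loss, drift leakage into the band, motion
# handling) and drive the observed-scale calibration of the generator.
.pipeline_calib <- function(spec, fs, montage, paradigm, n_rep = 3) {
  key <- paste("calib", fs, spec$fc_amplitude, spec$noise$white_sd,
               spec$noise$mayer_amp, spec$noise$resp_amp,
               spec$noise$cardiac_amp, spec$noise$drift_rw_sd,
               spec$noise$drift_slope_sd, spec$artifact_rate,
               spec$artifact_channel_frac, sep = "_")
  out <- .sim_cache[[key]]
  if (!is.null(out)) return(out)
  rois <- montage_rois()
  beta0 <- matrix(0, length(rois), 2,
                  dimnames = list(rois, c("freeze_induction", "normal_walk")))
  fcg <- spec$fc_structure[spec$fc_structure$group == "HC", ]
  tg0 <- data.frame(roi_a = fcg$roi_a, roi_b = fcg$roi_b, value = 0)
  dummy <- list(v_fluct_win = 1, v_indep_win = 0)
  measure <- function(s) {
    wv <- NULL; av <- NULL
    for (k in seq_len(n_rep)) {
      rec <- .session_core(s, "cal", "HC", beta0, tg0, fs, montage, paradigm,
                           noise_free = FALSE, calib = dummy)
      hb <- preprocess(rec)
      eps <- segment_epochs(hb, paradigm)
      x <- hb$data[eps$freeze_induction$task_idx, , "HbO2"]
      wv <- c(wv, colMeans(x^2) - colMeans(x)^2)
      av <- c(av, activation_value(hb, "freeze_induction", eps))
    }
    c(win = mean(wv), act = stats::var(av))
  }
  vA <- with_preserved_seed(424242L, measure(spec))
  s0 <- spec
  s0$fc_amplitude <- 1e-7
  vB <- with_preserved_seed(424243L, measure(s0))
  out <- list(v_fluct_win = max(vA[["win"]] - vB[["win"]], 1e-8),
              v_indep_win = vB[["win"]],
              v_fluct_act = max(vA[["act"]] - vB[["act"]], 0),
              v_indep_act = vB[["act"]])
  .sim_cache[[key]] <- out
  out
}

# ROI-level measurement SD of the activation estimate: the fluctuation
# component is correlated across an ROI's channels (approximately at the
# group's intra-ROI target), independent noise averages down with k.
.roi_meas_sd <- function(spec, group, fs, paradigm, montage) {
  v <- .pipeline_calib(spec, fs, montage, paradigm)
  fcg <- spec$fc_structure[spec$fc_structure$group == group, ]
  intra <- fcg[fcg$roi_a == fcg$roi_b, ]
  vapply(montage_rois(), function(r) {
    k <- length(montage$roi_map[[r]])
    rho <- intra$mean[intra$roi_a == r]
    rho <- if (length(rho)) rho[1] else 0
    sqrt(v$v_fluct_act * (1 + (k - 1) * rho) / k + v$v_indep_act / k)
  }, numeric(1))
}

# band-limited correlated fluctuation field: n x nch, channel covariance
# from corr matrix C, per-channel SD sigma, spectrum shaped by the
# one-pass Butterworth band magnitude (circular filtering; the process is
# stationary noise so no edge padding is needed)
.fluct_field <- function(n, nch, C, sigma, fs) {
  N <- stats::nextn(n, c(2, 3, 5))   # fast FFT length; excess truncated
  Z <- matrix(stats::rnorm(N * nch), N, nch)
  if (!identical(C, diag(nch))) {
    Z <- Z %*% chol(C)
  }
  g <- sqrt(.bandpass_response(N, fs, filter_params()$band,
                               filter_params()$order))
  X <- Re(stats::mvfft(stats::mvfft(Z) * g, inverse = TRUE)) / N
  X <- X[seq_len(n), , drop = FALSE]
  sds <- sqrt(colMeans(X^2) - colMeans(X)^2)
  X * rep(sigma / sds, each = n)
}

# physiological noise field: oscillations with per-channel phase, drift,
# white noise
.physio_noise <- function(n, nch, ns, fs) {
  t <- (seq_len(n) - 1) / fs
  osc <- function(freq, amp) {
    f <- freq * (1 + stats::rnorm(1, 0, 0.03))
    ph <- stats::runif(nch, 0, 2 * pi)
    amp * sin(outer(2 * pi * f * t, ph, `+`))
  }
  # random walk generated at 1 Hz and linearly interpolated (drift is
  # sub-0.01 Hz; the fine structure is irrelevant and removed by the
  # bandpass anyway)
  nc <- ceiling(n / fs) + 1L
  rw <- apply(matrix(stats::rnorm(nc * nch, 0, ns$drift_rw_sd), nc, nch),
              2, cumsum)
  pos <- 1 + t
  i1 <- pmin(floor(pos), nc - 1L); f <- pos - i1
  rw_fine <- rw[i1, , drop = FALSE] * (1 - f) + rw[i1 + 1L, , drop = FALSE] * f
  drift <- outer(t, stats::rnorm(nch, 0, ns$drift_slope_sd)) + rw_fine
  osc(ns$cardiac_freq, ns$cardiac_amp) + osc(ns$resp_freq, ns$resp_amp) +
    osc(ns$mayer_freq, ns$mayer_amp) + drift +
    matrix(stats::rnorm(n * nch, 0, ns$white_sd), n, nch)
}

# Subject-level latent channel correlation matrix. Drawn ROI-pair targets
# are stated on the observed scale (Pearson r of the analysed series in
# the freezing-induction window); latent region-pair correlations are
# solved by inverting the contamination model
#   r_AB = (c_AB V_f + cov_e(A, B)) / sqrt((V_f + v_n + v_e_A)(V_f + v_n + v_e_B))
# where V_f is the effective post-filter fluctuation variance, v_n the
# independent in-band noise variance, and v_e / cov_e the within-window
# variance and covariance of the evoked responses (constant within an ROI
# because the drive is region-wide). The channel matrix is then built via
# a region-factor parameterization -- channel i in region A is
# sqrt(a_A) F_A + sqrt(1 - a_A) e_i with Corr(F_A, F_B) = P_AB -- which is
# positive semi-definite by construction whenever the small factor
# correlation matrix P is, so per-subject draws never need a distorting
# projection of the full 48 x 48 matrix.
.latent_corr <- function(targets, montage, evoked_win, v_fluct, v_indep,
                         strict = FALSE) {
  labels <- montage$channels$roi
  gl <- c(montage_rois(), "NONE")
  ng <- length(gl)
  rep_ch <- vapply(gl, function(g) which(labels == g)[1], integer(1))
  ew <- evoked_win[, rep_ch, drop = FALSE]
  ew <- sweep(ew, 2, colMeans(ew))
  ce <- crossprod(ew) / (nrow(ew) - 1)          # region-level evoked cov
  v_tot <- v_fluct + v_indep + diag(ce)
  R <- matrix(NA_real_, ng, ng, dimnames = list(gl, gl))
  for (k in seq_len(nrow(targets))) {
    R[targets$roi_a[k], targets$roi_b[k]] <- targets$value[k]
    R[targets$roi_b[k], targets$roi_a[k]] <- targets$value[k]
  }
  if (anyNA(R)) stop("fc_structure does not cover every region pair")
  C6 <- (R * sqrt(outer(v_tot, v_tot)) - ce) / v_fluct
  C6[C6 > 0.95] <- 0.95
  C6[C6 < -0.95] <- -0.95
  gi <- match(labels, gl)
  C <- C6[gi, gi]
  diag(C) <- 1
  eg <- eigen(C, symmetric = TRUE)
  if (strict && min(eg$values) < -0.05 * max(eg$values))
    stop("infeasible correlation structure: latent channel covariance is ",
         "not positive semi-definite under the requested targets")
  if (min(eg$values) < 1e-6) {
    lam <- pmax(eg$values, 1e-6)
    C <- eg$vectors %*% (lam * t(eg$vectors))
    d <- sqrt(diag(C))
    C <- C / outer(d, d)
  }
  C
}

# hierarchical subject deviation: a global connectivity level (weight
# w_g), a per-region factor (w_r) and an independent pair residual (w_e);
# weights favour the global component because global moves preserve the
# positive-definiteness of the implied channel covariance
.fc_draw_z <- function(fcg) {
  w_g <- sqrt(0.7); w_r <- sqrt(0.2); w_e <- sqrt(0.1)
  regions <- unique(c(fcg$roi_a, fcg$roi_b))
  u <- stats::rnorm(1)
  v <- stats::setNames(stats::rnorm(length(regions)), regions)
  e <- stats::rnorm(nrow(fcg))
  vpair <- ifelse(fcg$roi_a == fcg$roi_b, v[fcg$roi_a],
                  (v[fcg$roi_a] + v[fcg$roi_b]) / sqrt(2))
  w_g * u + w_r * vpair + w_e * e
}

# Calibration of the draw-to-observation map, estimated once per noise
# configuration by replicating drawn-target sessions through the full
# analysis chain (pinned internal seed; caller's RNG preserved). For each
# ROI pair the observed value is regressed on the drawn target, giving
# (a) the per-pair residual variance (finite-window sampling noise) and
# (b) the response slope, pooled within intra/inter pair types (residual
# feasibility repairs attenuate coherent draws slightly). Subject-level
# draw SDs are deconvolved through this map so cohort-level observed SDs
# land on the targets. The group-mean structure is feasibility-checked
# strictly before any replication.
.fc_sampling_var <- function(spec, group, fs = 11,
                             montage = build_default_montage(),
                             paradigm = default_paradigm(), n_rep = 48) {
  fcg <- spec$fc_structure[spec$fc_structure$group == group, ]
  key <- paste("fcsamp", group, fs, spec$fc_amplitude,
               spec$noise$white_sd, spec$noise$mayer_amp, spec$artifact_rate,
               signif(sum(fcg$mean * seq_len(nrow(fcg))), 10),
               signif(sum(fcg$sd^2), 10),
               signif(sum(spec$activation_effects$mean^2), 10), sep = "_")
  out <- .sim_cache[[key]]
  if (!is.null(out)) return(out)
  rois <- montage_rois()
  ae <- spec$activation_effects[spec$activation_effects$group == group, ]
  beta <- sapply(c("freeze_induction", "normal_walk"), function(cond) {
    sub <- ae[ae$condition == cond, ]
    sub$mean[match(rois, sub$roi)]
  })
  rownames(beta) <- rois
  fixed_targets <- data.frame(roi_a = fcg$roi_a, roi_b = fcg$roi_b,
                              value = fcg$mean)
  # feasibility of the group-mean structure is checked once, strictly
  calib <- .pipeline_calib(spec, fs, montage, paradigm)
  resp <- .drive_response(fs, paradigm, spec$hrf)
  amp <- t(solve(resp$response, t(beta)))
  labels <- montage$channels$roi
  drive_ch <- matrix(0, nrow(montage$channels), 2)
  for (r in rois) drive_ch[labels == r, ] <- rep(amp[r, ], each = sum(labels == r))
  ew <- resp$filtered[resp$windows$freeze_induction$task, ] %*% t(drive_ch)
  invisible(.latent_corr(fixed_targets, montage, ew, calib$v_fluct_win,
                         calib$v_indep_win, strict = TRUE))
  nm <- paste0(fcg$roi_a, "-", fcg$roi_b)
  fit_pass <- function(sd_draw, seed) with_preserved_seed(seed, {
    drawn <- matrix(0, n_rep, nrow(fcg))
    obs <- matrix(0, n_rep, nrow(fcg))
    for (k in seq_len(n_rep)) {
      tg <- data.frame(roi_a = fcg$roi_a, roi_b = fcg$roi_b,
                       value = fcg$mean + sd_draw * .fc_draw_z(fcg))
      rec <- .session_core(spec, "cal", group, beta, tg, fs, montage,
                           paradigm, noise_free = FALSE)
      hb <- preprocess(rec)
      pr <- roi_pair_fc(suppressWarnings(fc_matrix(hb, "freeze_induction")),
                        montage)
      prnm <- paste0(pr$roi_a, "-", pr$roi_b)
      drawn[k, ] <- tg$value
      obs[k, ] <- pr$value[match(nm, prnm)]
    }
    v_resid <- numeric(nrow(fcg))
    slope <- numeric(nrow(fcg))
    for (j in seq_len(nrow(fcg))) {
      if (all(is.na(obs[, j]))) { v_resid[j] <- 0; slope[j] <- 1; next }
      f <- stats::lm.fit(cbind(1, drawn[, j]), obs[, j])
      slope[j] <- min(max(f$coefficients[2], 0.5), 1.2)
      v_resid[j] <- sum(f$residuals^2) / (n_rep - 2)
    }
    list(v_resid = stats::setNames(v_resid, nm),
         slope = stats::setNames(slope, nm))
  })
  shrink <- function(cal) {
    sd_lat <- sqrt(pmax(fcg$sd^2 - cal$v_resid, (0.25 * fcg$sd)^2)) /
      cal$slope
    pmin(sd_lat, 1.5 * fcg$sd)
  }
  # two passes: residual variance is mildly heteroscedastic in the draw
  # scale, so the second pass re-estimates the map at the draw SD that
  # will actually be used
  p1 <- fit_pass(fcg$sd, 88211L)
  out <- fit_pass(shrink(p1), 88212L)
  .sim_cache[[key]] <- out
  out
}

# Draw per-subject observed-scale targets. Between-subject variability is
# hierarchical -- a global connectivity level shared by every pair, a
# per-region factor shared by the region's pairs, and a small independent
# pair residual -- so a subject's drawn targets move coherently and the
# implied channel covariance stays (near-)positive-definite. The draw SD
# of each pair is shrunk by the empirically calibrated window-sampling
# variance so the cohort-level observed SDs land on the targets.
.draw_fc_targets <- function(spec, group, fs = 11,
                             montage = build_default_montage(),
                             paradigm = default_paradigm()) {
  fcg <- spec$fc_structure[spec$fc_structure$group == group, ]
  cal <- .fc_sampling_var(spec, group, fs, montage, paradigm)
  nm <- paste0(fcg$roi_a, "-", fcg$roi_b)
  va <- ifelse(nm %in% names(cal$v_resid), cal$v_resid[nm], 0)
  sl <- ifelse(nm %in% names(cal$slope), cal$slope[nm], 1)
  sd_lat <- sqrt(pmax(fcg$sd^2 - va, (0.25 * fcg$sd)^2)) / sl
  sd_lat <- pmin(sd_lat, 1.5 * fcg$sd)
  data.frame(roi_a = fcg$roi_a, roi_b = fcg$roi_b,
             value = fcg$mean + sd_lat * .fc_draw_z(fcg))
}

#' Inject a motion artifact into a single series
#'
#' `"spike"` adds a transient Gaussian bump of at most 1 s; `"shift"` adds
#' a sustained baseline step starting at `t`. A ground-truth logical mask
#' covering the perturbed interval (for a shift, 1 s either side of the
#' step) is returned alongside.
#'
#' @param series Numeric vector (optical-density units).
#' @param kind `"spike"` or `"shift"`.
#' @param t Event time in seconds; must lie inside the recording.
#' @param magnitude Artifact amplitude in the units of `series`.
#' @param fs Sampling rate in Hz.
#' @return List with elements `series` and `mask`.
#' @export
inject_artifact <- function(series, kind = c("spike", "shift"), t, magnitude,
                            fs) {
  kind <- match.arg(kind)
  n <- length(series)
  if (t < 0 || t > n / fs) stop("artifact time ", t, " s outside recording")
  tt <- (seq_len(n) - 1) / fs
  mask <- rep(FALSE, n)
  if (kind == "spike") {
    shape <- exp(-0.5 * ((tt - t) / 0.12)^2)
    shape[abs(tt - t) > 0.5] <- 0
    series <- series + magnitude * shape
    if (magnitude != 0) mask <- abs(tt - t) <= 0.5
  } else {
    series <- series + magnitude * (tt >= t)
    if (magnitude != 0) mask <- abs(tt - t) <= 1.0
  }
  list(series = series, mask = mask)
}

#' Simulate one raw-intensity session
#'
#' Generates a full 270-s dual-wavelength recording at the montage's 48
#' channels for one subject, with evoked responses, latent connectivity
#' structure, physiological noise and motion artifacts per `spec`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier string.
#' @param group `"HC"` or `"PD_FOG"`.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param fs Sampling rate in Hz.
#' @param montage,paradigm Montage and paradigm to simulate under.
#' @param noise_free If `TRUE`, suppress all noise, fluctuations and
#'   artifacts (evoked component only; used for round-trip checks).
#' @return An `fnirs_recording` with a `ground_truth` attribute (drawn
#'   activation effects, connectivity targets, artifact events and mask).
#' @export
simulate_session <- function(spec, subject_id, group = c("HC", "PD_FOG"),
                             seed = 1, fs = 11,
                             montage = build_default_montage(),
                             paradigm = default_paradigm(),
                             noise_free = FALSE) {
  group <- match.arg(group)
  roi_meas_sd <- if (noise_free) 0
                 else .roi_meas_sd(spec, group, fs, paradigm, montage)
  if (!noise_free) .fc_sampling_var(spec, group, fs, montage, paradigm)

  set.seed(seed)
  rois <- montage_rois()

  # per-subject observed-scale activation targets; between-subject draw
  # SDs are shrunk by the ROI-level measurement SD so the cohort-level
  # observed SDs land on the targets
  ae <- spec$activation_effects
  ae <- ae[ae$group == group, ]
  beta <- sapply(c("freeze_induction", "normal_walk"), function(cond) {
    sub <- ae[ae$condition == cond, ]
    mu <- sub$mean[match(rois, sub$roi)]
    if (noise_free) return(mu)  # exact nominal effects for round trips
    sdv <- sub$sd[match(rois, sub$roi)]
    sd_lat <- sqrt(pmax(sdv^2 - roi_meas_sd^2, (0.3 * sdv)^2))
    stats::rnorm(length(rois), mu, sd_lat)
  })
  rownames(beta) <- rois
  fc_targets <- if (noise_free) NULL
                else .draw_fc_targets(spec, group, fs, montage, paradigm)
  .session_core(spec, subject_id, group, beta, fc_targets, fs, montage,
                paradigm, noise_free)
}

# Build the recording from drawn subject-level targets, consuming the
# caller's RNG stream.
.session_core <- function(spec, subject_id, group, beta, fc_targets, fs,
                          montage, paradigm, noise_free, calib = NULL) {
  resp <- .drive_response(fs, paradigm, spec$hrf)
  n <- resp$n
  if (is.null(calib) && !noise_free)
    calib <- .pipeline_calib(spec, fs, montage, paradigm)
  nch <- nrow(montage$channels)
  labels <- montage$channels$roi
  rois <- montage_rois()

  # solve drive amplitudes so pipeline estimates equal the targets
  amp <- t(solve(resp$response, t(beta)))   # roi x (freeze, normal)
  drive_ch <- matrix(0, nch, 2)
  for (r in rois) drive_ch[labels == r, ] <- rep(amp[r, ], each = sum(labels == r))
  evoked <- resp$shapes %*% t(drive_ch)     # n x nch

  artifact_mask <- matrix(FALSE, n, nch)
  events <- data.frame(time = numeric(0), kind = character(0),
                       magnitude = numeric(0))
  if (noise_free) {
    hbo <- evoked
    hhb <- -hbo / 3
  } else {
    evoked_win <- (resp$filtered[resp$windows$freeze_induction$task, ] %*%
                     t(drive_ch))
    C <- .latent_corr(fc_targets, montage, evoked_win,
                      calib$v_fluct_win, calib$v_indep_win)
    hbo <- evoked + .fluct_field(n, nch, C, spec$fc_amplitude, fs) +
      .physio_noise(n, nch, spec$noise, fs)
    hhb <- -hbo / 3 + matrix(stats::rnorm(n * nch, 0, 0.02), n, nch)
  }

  conc <- array(c(hbo, hhb), dim = c(n, nch, 2),
                dimnames = list(NULL, NULL, c("HbO2", "HHb")))
  od <- mbll_forward(conc, mbll_params(separation = montage$separation))

  if (!noise_free && spec$artifact_rate > 0) {
    n_ev <- stats::rpois(1, spec$artifact_rate * n / fs / 60)
    if (n_ev > 0) {
      od_sd <- sqrt(colMeans(od[, , 1]^2) - colMeans(od[, , 1])^2)
      tt <- (seq_len(n) - 1) / fs
      for (e in seq_len(n_ev)) {
        t_e <- stats::runif(1, 5, n / fs - 5)
        kind <- sample(c("spike", "shift"), 1)
        chs <- sample(nch, max(1, round(spec$artifact_channel_frac * nch)))
        mag_f <- stats::runif(1, 6, 12)
        mags <- mag_f * od_sd[chs] *
          sample(c(-1, 1), length(chs), replace = TRUE)
        if (kind == "spike") {
          supp <- which(abs(tt - t_e) <= 0.5)
          shape <- exp(-0.5 * ((tt[supp] - t_e) / 0.12)^2)
          mrows <- supp
        } else {
          supp <- which(tt >= t_e)
          shape <- rep(1, length(supp))
          mrows <- which(abs(tt - t_e) <= 1.0)
        }
        bump <- outer(shape, mags)
        for (wl in 1:2) od[supp, chs, wl] <- od[supp, chs, wl] + bump
        artifact_mask[mrows, chs] <- TRUE
        events <- rbind(events, data.frame(time = t_e, kind = kind,
                                           magnitude = mag_f))
      }
    }
  }

  i0 <- matrix(stats::runif(nch * 2, 500, 1500), nch, 2)
  intensity <- array(0, dim = dim(od))
  for (wl in 1:2)
    intensity[, , wl] <- 10^(-od[, , wl]) * rep(i0[, wl], each = n)

  rec <- new_recording(intensity, fs = fs, subject_id = subject_id,
                       group = group, paradigm = paradigm)
  attr(rec, "ground_truth") <- list(
    beta = beta, fc_targets = fc_targets, artifact_events = events,
    artifact_mask = artifact_mask)
  rec
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` sessions per group plus matched gait tables.
#' The whole cohort is a pure function of `(spec, spec$seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param fs Sampling rate in Hz.
#' @param montage,paradigm Montage and paradigm.
#' @return List with `recordings` (list of `fnirs_recording`), `gait`
#'   (data.frame of gait records) and `subject_seeds`.
#' @export
simulate_cohort <- function(spec, fs = 11, montage = build_default_montage(),
                            paradigm = default_paradigm()) {
  set.seed(spec$seed)
  n <- spec$n_per_group
  groups <- rep(c("HC", "PD_FOG"), each = n)
  ids <- c(sprintf("HC%02d", seq_len(n)), sprintf("PD%02d", seq_len(n)))
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
  gait <- simulate_gait(spec, ids, groups)
  recordings <- vector("list", 2 * n)
  for (i in seq_along(ids)) {
    recordings[[i]] <- simulate_session(spec, ids[i], groups[i],
                                        seed = seeds[i], fs = fs,
                                        montage = montage, paradigm = paradigm)
  }
  list(recordings = recordings, gait = gait, subject_seeds = seeds)
}

#' Simulate gait-parameter tables
#'
#' Draws per-subject gait records for every condition/intervention cell in
#' the spec's gait targets, with a stable subject random effect inducing
#' the within-subject pairing across cells. Freezing-episode counts are
#' Poisson draws.
#'
#' @param spec A [cohort_spec()].
#' @param subject_ids,groups Parallel vectors of ids and group labels.
#' @return data.frame with one row per subject x condition x intervention.
#' @export
simulate_gait <- function(spec, subject_ids, groups) {
  ge <- spec$gait_effects
  params <- setdiff(unique(ge$parameter), "fog_count")
  rho <- spec$gait_subject_re
  out <- list()
  for (i in seq_along(subject_ids)) {
    g <- groups[i]
    cells <- unique(ge[ge$group == g, c("condition", "intervention")])
    # subject effect shared across cells, parameter-wise
    z_subj <- stats::setNames(stats::rnorm(length(params)), params)
    for (k in seq_len(nrow(cells))) {
      sub <- ge[ge$group == g & ge$condition == cells$condition[k] &
                  ge$intervention == cells$intervention[k], ]
      vals <- sapply(params, function(p) {
        r <- sub[sub$parameter == p, ]
        v <- r$mean + r$sd * (sqrt(rho) * z_subj[[p]] +
                                sqrt(1 - rho) * stats::rnorm(1))
        max(v, 0)
      })
      lam <- sub$mean[sub$parameter == "fog_count"]
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subject_ids[i], group = g,
        condition = cells$condition[k], intervention = cells$intervention[k],
        t(vals), fog_count = stats::rpois(1, lam))
    }
  }
  do.call(rbind, out)
}
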