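# Preprocessing chain: channel quality control on raw intensity,
# optical-density conversion, motion-artifact detection and spline
# correction in the OD domain, MBLL inversion, zero-phase bandpass.

#' Motion-artifact detection parameters
#'
#' Within each sliding window of `t_motion` seconds a channel is flagged
#' when the signal range exceeds `stdev_thresh` times the channel's global
#' SD or exceeds `amp_thresh` optical-density units; flagged instants are
#' dilated by `t_mask` seconds on each side.
#'
#' @param stdev_thresh Multiple of channel SD. Default 6.0.
#' @param amp_thresh Absolute OD amplitude threshold. Default 0.5.
#' @param t_motion Detection window length in seconds. Default 0.5.
#' @param t_mask Dilation in seconds. Default 1.0.
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(stdev_thresh = 6.0, amp_thresh = 0.5,
                          t_motion = 0.5, t_mask = 1.0) {
  stopifnot(stdev_thresh > 0, amp_thresh > 0, t_motion > 0, t_mask > 0)
  structure(list(stdev_thresh = stdev_thresh, amp_thresh = amp_thresh,
                 t_motion = t_motion, t_mask = t_mask),
            class = "motion_params")
}

#' Channel quality control by coefficient of variation
#'
#' Computes `CV = 100 * sd / mean` per channel and wavelength over the full
#' raw-intensity recording. A channel is retained iff its CV is at or below
#' the threshold at *both* wavelengths (the exclusion rule is strictly
#' `CV > threshold`). Channels whose mean intensity is zero or negative
#' have undefined CV and are excluded with a reason code.
#'
#' @param rec An `fnirs_recording`.
#' @param threshold CV threshold in percent. Default 14.
#' @return A `qc_report` data.frame: `channel`, `cv_730`, `cv_850`
#'   (columns named after the actual wavelengths), `retained`, `reason`.
#' @export
channel_qc <- function(rec, threshold = 14) {
  stopifnot(inherits(rec, "fnirs_recording"))
  d <- dim(rec$data)
  cv <- sapply(seq_len(d[3]), function(wl) {
    x <- rec$data[, , wl, drop = TRUE]
    mu <- colMeans(x)
    sdv <- sqrt(colMeans(x^2) - mu^2) * sqrt(d[1] / (d[1] - 1))
    ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  })
  undefined <- apply(is.na(cv), 1, any)
  retained <- !undefined & apply(cv <= threshold, 1, all)
  rep <- data.frame(channel = seq_len(d[2]), cv, retained = retained,
                    reason = ifelse(undefined, "undefined_cv",
                                    ifelse(retained, "", "cv_above_threshold")))
  names(rep)[2:(1 + d[3])] <- paste0("cv_", rec$wavelengths)
  attr(rep, "threshold") <- threshold
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Convert raw intensity to optical-density changes
#'
#' `dOD(t, lambda) = -log10(I(t, lambda) / mean(I(lambda)))`, per channel,
#' with the mean taken over the full recording.
#'
#' @param rec An `fnirs_recording` (all intensities strictly positive).
#' @return Array `[time, channel, wavelength]` of dOD.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (any(rec$data <= 0)) stop("non-positive intensity in recording")
  od <- rec$data
  n <- dim(od)[1]
  for (wl in seq_len(dim(od)[3])) {
    x <- od[, , wl, drop = TRUE]
    od[, , wl] <- -log10(x * rep(1 / colMeans(x), each = n))
  }
  od
}

# rolling range (max - min) over a trailing window of w samples, per column
.rolling_range <- function(x, w) rolling_range_cpp(x, as.integer(w))

#' Detect motion artifacts in optical-density series
#'
#' Flags, per channel, sliding windows whose signal range exceeds either
#' `stdev_thresh` times the channel's global SD or `amp_thresh` OD units,
#' then dilates flagged instants by `t_mask` seconds. For dual-wavelength
#' input a channel instant is flagged if either wavelength triggers.
#'
#' @param od `[time, channel, wavelength]` array or `time x channel` matrix
#'   of OD.
#' @param fs Sampling rate in Hz.
#' @param params A [motion_params()] object.
#' @return Logical `time x channel` matrix; `TRUE` marks artifact samples.
#' @export
detect_motion_artifacts <- function(od, fs, params = motion_params()) {
  if (length(dim(od)) == 3) {
    m <- detect_motion_artifacts(od[, , 1, drop = TRUE], fs, params)
    for (wl in 2:dim(od)[3])
      m <- m | detect_motion_artifacts(od[, , wl, drop = TRUE], fs, params)
    return(m)
  }
  od <- as.matrix(od)
  n <- nrow(od)
  w <- max(2L, round(params$t_motion * fs))
  rng <- .rolling_range(od, w)
  mu <- colMeans(od)
  sdv <- sqrt(pmax(colMeans(od^2) - mu^2, 0)) * sqrt(n / (n - 1))
  thr <- pmin(params$stdev_thresh * sdv, params$amp_thresh)
  flag <- sweep(rng, 2, thr, `>`)
  # a trailing window flags all samples it covers, then +/- t_mask dilation
  wd <- (w - 1L) + round(params$t_mask * fs)   # backward reach
  wu <- round(params$t_mask * fs)              # forward reach
  out <- matrix(FALSE, n, ncol(flag))
  for (ch in which(colSums(flag) > 0)) {
    ts <- which(flag[, ch])
    lo <- pmax(ts - wd, 1L)
    hi <- pmin(ts + wu, n)
    cover <- cumsum(tabulate(lo, n)) - c(0, cumsum(tabulate(hi, n)))[seq_len(n)]
    out[, ch] <- cover > 0
  }
  out
}

# correct one channel's OD series given its artifact mask
.spline_correct_vec <- function(x, mask, fs, spar) {
  if (!any(mask)) return(x)
  n <- length(x)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  win <- max(2L, round(1.0 * fs))      # reference window for re-leveling
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- x[i0:i1]
    len <- length(seg)
    # reference level: preceding clean samples, else following
    if (i0 > 1) {
      ref <- x[max(1, i0 - win):(i0 - 1)]
    } else {
      ref <- x[(i1 + 1):min(n, i1 + win)]
    }
    m_ref <- mean(ref)
    if (len >= 8) {
      fit <- stats::smooth.spline(seq_len(len), seg, spar = spar)$y
      newseg <- seg - fit + m_ref
    } else {
      newseg <- rep(m_ref, len)
    }
    # offset trailing samples so the series stays continuous at the
    # segment's trailing edge (removes sustained baseline steps)
    if (i1 < n) {
      after <- x[(i1 + 1):min(n, i1 + win)]
      delta <- mean(after) - m_ref
      x[(i1 + 1):n] <- x[(i1 + 1):n] - delta
    }
    x[i0:i1] <- newseg
  }
  x
}

#' Correct motion artifacts by cubic spline subtraction
#'
#' For every flagged segment, fits a cubic smoothing spline to the segment,
#' subtracts it, and re-levels the segment to the mean of the preceding
#' clean second (the following one for segments at the recording start).
#' Samples after the segment are offset so the series is continuous at the
#' segment's trailing edge; for transient artifacts this offset is
#' negligible, while sustained baseline steps are removed by it.
#'
#' @param od OD array `[time, channel, wavelength]` or `time x channel`
#'   matrix.
#' @param mask Logical `time x channel` matrix from
#'   [detect_motion_artifacts()].
#' @param fs Sampling rate in Hz.
#' @param spar Smoothing parameter of [stats::smooth.spline()], on R's
#'   spar scale where larger is smoother. Default 0: a closely tracking
#'   fit, equivalent to a near-interpolating smoothing parameter (0.99)
#'   in conventions where 1 denotes the interpolant. The fit must follow
#'   the artifact trajectory -- including sharp baseline steps -- so that
#'   subtracting it removes the artifact rather than the signal.
#' @return Corrected object of the same shape as `od`.
#' @export
spline_correct <- function(od, mask, fs, spar = 0) {
  if (length(dim(od)) == 3) {
    for (wl in seq_len(dim(od)[3]))
      od[, , wl] <- spline_correct(od[, , wl, drop = TRUE], mask, fs, spar)
    return(od)
  }
  od <- as.matrix(od)
  stopifnot(identical(dim(mask), dim(od)))
  for (ch in which(colSums(mask) > 0))
    od[, ch] <- .spline_correct_vec(od[, ch], mask[, ch], fs, spar)
  od
}

#' Run the full preprocessing chain
#'
#' Channel QC on raw intensity, OD conversion, motion-artifact detection
#' and spline correction (OD domain), MBLL inversion to hemoglobin
#' concentration changes, and zero-phase Butterworth bandpass. Channels
#' excluded by QC are set to `NA` so they carry no finite values
#' downstream.
#'
#' @param rec An `fnirs_recording`.
#' @param qc_threshold CV threshold in percent.
#' @param motion A [motion_params()] object, or `NULL` to skip motion
#'   handling.
#' @param filter A [filter_params()] object.
#' @param mbll_par An [mbll_params()] object.
#' @return An object of class `hb_series`: `data`
#'   `[time, channel, chromophore]` in micromol/L, `fs`, `qc`
#'   (the QC report), `artifact_mask`.
#' @export
preprocess <- function(rec, qc_threshold = 14, motion = motion_params(),
                       filter = filter_params(), mbll_par = mbll_params()) {
  stopifnot(inherits(rec, "fnirs_recording"))
  qc <- channel_qc(rec, qc_threshold)
  od <- intensity_to_od(rec)
  if (!is.null(motion)) {
    mask <- detect_motion_artifacts(od, rec$fs, motion)
    if (any(mask)) od <- spline_correct(od, mask, rec$fs)
  } else {
    mask <- matrix(FALSE, dim(od)[1], dim(od)[2])
  }
  conc <- mbll(od, mbll_par)
  conc <- bandpass(conc, rec$fs, filter)
  conc[, !qc$retained, ] <- NA_real_
  structure(
    list(data = conc, fs = rec$fs, subject_id = rec$subject_id,
         group = rec$group, paradigm = rec$paradigm, qc = qc,
         artifact_mask = mask),
    class = "hb_series"
  )
}

#' @export
print.hb_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Hemoglobin series '%s' (%s): %d channels, %.1f s at %g Hz; %d retained, %.2f%% samples artifact-flagged\n",
    x$subject_id, x$group, d[2], d[1] / x$fs, x$fs, sum(x$qc$retained),
    100 * mean(x$artifact_mask)))
  invisible(x)
}
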