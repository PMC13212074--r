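# Canonical double-gamma hemodynamic response function.

#' Hemodynamic response function specification
#'
#' Double-gamma HRF with an onset delay: the response begins
#' `onset_delay` seconds after neural activation and peaks at
#' `time_to_peak` seconds after neural activation (defaults 1.5 s and
#' 5.5 s, inside the physiological 1--2 s latency / 4--7 s peak range),
#' followed by a post-stimulus undershoot.
#'
#' @param onset_delay Seconds between neural activation and response onset.
#' @param time_to_peak Seconds between neural activation and response peak.
#' @param undershoot_ratio Amplitude ratio of the undershoot gamma.
#' @param shape_peak,shape_undershoot Gamma shape parameters of the peak and
#'   undershoot components.
#' @return A list of class `hrf_spec`.
#' @export
hrf_spec <- function(onset_delay = 1.5, time_to_peak = 5.5,
                     undershoot_ratio = 1 / 6,
                     shape_peak = 6, shape_undershoot = 16) {
  stopifnot(onset_delay >= 0, time_to_peak > onset_delay,
            undershoot_ratio >= 0)
  structure(list(onset_delay = onset_delay, time_to_peak = time_to_peak,
                 undershoot_ratio = undershoot_ratio,
                 shape_peak = shape_peak,
                 shape_undershoot = shape_undershoot),
            class = "hrf_spec")
}

#' Sampled HRF kernel
#'
#' @param spec An [hrf_spec()].
#' @param fs Sampling rate in Hz.
#' @param duration Kernel length in seconds (covers peak and undershoot).
#' @return Numeric vector, normalized to unit peak amplitude.
#' @export
hrf_kernel <- function(spec = hrf_spec(), fs, duration = 32) {
  t <- seq(0, duration, by = 1 / fs)
  tp <- pmax(t - spec$onset_delay, 0)
  rate <- (spec$shape_peak - 1) / (spec$time_to_peak - spec$onset_delay)
  g1 <- stats::dgamma(tp, shape = spec$shape_peak, rate = rate)
  g2 <- stats::dgamma(tp, shape = spec$shape_undershoot, rate = rate)
  h <- g1 / max(g1) - spec$undershoot_ratio * g2 / max(g2)
  h / max(h)
}

# causal convolution of a drive vector with a kernel
convolve_drive <- function(drive, kernel) {
  as.numeric(stats::filter(drive, kernel, method = "convolution",
                           sides = 1, circular = FALSE)) -> y
  # leading samples where the kernel window is incomplete
  nk <- length(kernel)
  if (nk > 1) {
    head_vals <- vapply(seq_len(nk - 1), function(i)
      sum(kernel[seq_len(i)] * drive[i:1]), numeric(1))
    y[seq_len(nk - 1)] <- head_vals
  }
  y
}
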