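# Zero-phase Butterworth bandpass filtering.
#
# The filter is designed in-package by the standard analog-prototype /
# bandpass-transform / bilinear route and factored into cascaded
# second-order sections; it is applied forward-backward (zero phase) in
# compiled code, with odd-reflection padding and steady-state initial
# conditions to suppress start-up transients. Direct-form application of
# a single sixth-order polynomial is avoided: at a 0.01 Hz cutoff on an
# 11 Hz clock its coefficient representation is too ill-conditioned.

#' Bandpass filter parameters
#'
#' @param band Length-2 numeric, passband in Hz. Default `c(0.01, 0.2)`,
#'   which removes slow drift below 0.01 Hz and cardiac (~1 Hz),
#'   respiratory (~0.3 Hz) and other physiological noise above 0.2 Hz while
#'   retaining the task-related hemodynamic band.
#' @param order Butterworth order of the underlying one-pass filter
#'   (effective order doubles under zero-phase application). Default 3.
#' @param zero_phase Logical; the implementation is inherently zero-phase
#'   and only `TRUE` is supported.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(band = c(0.01, 0.2), order = 3, zero_phase = TRUE) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1], order >= 1,
            isTRUE(zero_phase))
  structure(list(band = band, order = order, zero_phase = TRUE),
            class = "filter_params")
}

#' Squared-magnitude response of the digital Butterworth bandpass
#'
#' Exact magnitude-squared response (i.e. the zero-phase forward-backward
#' gain) of an order-`order` Butterworth bandpass designed by bilinear
#' transform, evaluated at frequencies `f` (Hz) for sampling rate `fs`.
#'
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param band Passband in Hz.
#' @param order Filter order.
#' @return Numeric vector of gains in `[0, 1]`.
#' @export
butter_bandpass_gain <- function(f, fs, band = c(0.01, 0.2), order = 3) {
  # prewarped analog frequencies of the bilinear design
  Om  <- tan(pi * f / fs)
  Om1 <- tan(pi * band[1] / fs)
  Om2 <- tan(pi * band[2] / fs)
  B <- Om2 - Om1
  O0sq <- Om1 * Om2
  q <- (Om^2 - O0sq) / (B * Om)
  g <- 1 / (1 + q^(2 * order))     # |H|^2 = forward-backward amplitude gain
  g[Om == 0] <- 0
  g
}

.filter_cache <- new.env(parent = emptyenv())

# Butterworth bandpass as second-order sections: analog lowpass prototype
# poles, analog bandpass transform (order doubles), bilinear transform,
# conjugate-pair grouping. Every section carries one zero at z = 1 and
# one at z = -1; gain is normalized to 1 at the prewarped center
# frequency and distributed evenly over the sections.
.butter_bp_sos <- function(band, order, fs) {
  k <- seq_len(order)
  p_lp <- exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * order)))
  w1 <- 2 * fs * tan(pi * band[1] / fs)
  w2 <- 2 * fs * tan(pi * band[2] / fs)
  B <- w2 - w1
  w0 <- sqrt(w1 * w2)
  pa <- complex(0)
  for (p in p_lp) {
    d <- sqrt((p * B / 2)^2 - w0^2)
    pa <- c(pa, p * B / 2 + d, p * B / 2 - d)
  }
  pz <- (1 + pa / (2 * fs)) / (1 - pa / (2 * fs))
  # group digital poles into conjugate (or real) pairs
  used <- rep(FALSE, length(pz))
  pairs <- list()
  for (i in seq_along(pz)) {
    if (used[i]) next
    cand <- which(!used & seq_along(pz) != i)
    j <- cand[which.min(abs(pz[cand] - Conj(pz[i])))]
    used[c(i, j)] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(pz[i], pz[j])
  }
  sos <- t(vapply(pairs, function(pp)
    c(1, 0, -1, 1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2])), numeric(6)))
  wc <- 2 * atan(w0 / (2 * fs))
  z <- exp(1i * wc)
  h <- prod(apply(sos, 1, function(s)
    (s[1] * z^2 + s[2] * z + s[3]) / (s[4] * z^2 + s[5] * z + s[6])))
  g <- (1 / Mod(h))^(1 / nrow(sos))
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

# steady-state step-response state of one section (lfilter_zi)
.sos_zi <- function(s) {
  b <- s[1:3]; a <- s[4:6]
  A <- rbind(-a[2:3], c(1, 0))
  solve(diag(2) - t(A), b[2:3] - a[2:3] * b[1])
}

.sos_design <- function(band, order, fs) {
  key <- paste("sos", band[1], band[2], order, fs, sep = "_")
  d <- .filter_cache[[key]]
  if (is.null(d)) {
    sos <- .butter_bp_sos(band, order, fs)
    zi <- t(apply(sos, 1, .sos_zi))
    d <- list(sos = sos, zi = zi)
    .filter_cache[[key]] <- d
  }
  d
}

# core: filter columns of a matrix, pad_s seconds of odd reflection
.bandpass_mat <- function(x, fs, band, order, pad_s = 120) {
  n <- nrow(x)
  npad <- min(n - 2L, ceiling(pad_s * fs))
  d <- .sos_design(band, order, fs)
  sosfiltfilt_cpp(x, d$sos, d$zi, as.integer(npad))
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the configured zero-phase Butterworth bandpass to every channel
#' (and chromophore, for 3-d arrays). Input may be a numeric vector, a
#' `time x channel` matrix, or a `[time, channel, chromophore]` array.
#'
#' @param x Series to filter.
#' @param fs Sampling rate in Hz; must satisfy `fs / 2 > band[2]`.
#' @param params A [filter_params()] object.
#' @return Filtered object of the same shape as `x`.
#' @export
bandpass <- function(x, fs, params = filter_params()) {
  stopifnot(fs / 2 > params$band[2])
  n <- if (is.null(dim(x))) length(x) else dim(x)[1]
  if (n < 12 * params$order)
    stop("series too short for order-", params$order,
         " bandpass filtering; pad the series or lower the order")
  if (is.null(dim(x))) {
    drop(.bandpass_mat(matrix(x, ncol = 1), fs, params$band, params$order))
  } else if (length(dim(x)) == 2) {
    .bandpass_mat(x, fs, params$band, params$order)
  } else {
    out <- x
    for (k in seq_len(dim(x)[3]))
      out[, , k] <- .bandpass_mat(x[, , k], fs, params$band, params$order)
    out
  }
}

# FFT response used by the simulator to shape stationary noise fields
# (circular filtering is exact for stationary noise; no edges involved)
.bandpass_response <- function(N, fs, band, order) {
  key <- paste("resp", N, fs, band[1], band[2], order, sep = "_")
  m <- .filter_cache[[key]]
  if (is.null(m)) {
    f <- c(0:(ceiling(N / 2) - 1), -(floor(N / 2):1)) * fs / N
    m <- butter_bandpass_gain(abs(f), fs, band, order)
    .filter_cache[[key]] <- m
  }
  m
}
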