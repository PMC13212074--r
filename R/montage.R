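# Montage and task-paradigm definitions.
#
# Channel numbering is 1-based throughout the user-facing API, matching the
# convention used in published channel tables for this montage; internal
# matrices are indexed by position with channel id == column index.

# ROI membership of the 48-channel montage. 39 channels carry an ROI label,
# the remaining 9 are recorded but belong to no region of interest.
.roi_channels <- list(
  PFC = c(4L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 22L, 23L, 24L, 25L, 26L, 27L),
  PMC = c(19L, 30L, 34L, 35L, 36L, 41L, 42L, 43L),
  M1  = c(37L, 44L),
  S1  = c(31L, 32L, 33L, 39L, 40L),
  TLC = c(1L, 2L, 3L, 5L, 13L, 15L, 16L, 17L, 18L, 29L)
)

#' Region-of-interest names used by the default montage
#'
#' @return Character vector of ROI labels in canonical order.
#' @export
montage_rois <- function() names(.roi_channels)

#' Build the default 48-channel walking-task montage
#'
#' Constructs the montage used throughout the package: 48 measurement
#' channels formed from 24 sources and 16 detectors at 3 cm separation,
#' with channels grouped into five cortical regions of interest --
#' prefrontal (PFC), premotor (PMC), primary motor (M1), primary
#' somatosensory (S1) and temporal (TLC) cortex. Nine channels carry no ROI
#' label and are retained only for channel-level analyses.
#'
#' Source/detector indices are laid out on a regular grid; they are montage
#' metadata only and never enter any computation.
#'
#' @param separation Source-detector separation in cm.
#' @return An object of class `fnirs_montage` with elements `channels`
#'   (data.frame: `id`, `source_id`, `detector_id`, `roi`), `roi_map`
#'   (named list of channel-id vectors), `n_sources`, `n_detectors`,
#'   `separation`.
#' @examples
#' m <- build_default_montage()
#' roi_of(m, 37)           # "M1"
#' length(m$roi_map$PFC)   # 14
#' @export
build_default_montage <- function(separation = 3.0) {
  n_ch <- 48L
  roi <- rep("NONE", n_ch)
  for (r in names(.roi_channels)) roi[.roi_channels[[r]]] <- r
  channels <- data.frame(
    id = seq_len(n_ch),
    source_id = rep(1:24, each = 2L),
    detector_id = ((seq_len(n_ch) - 1L) %% 16L) + 1L,
    roi = roi,
    stringsAsFactors = FALSE
  )
  m <- structure(
    list(
      n_sources = 24L,
      n_detectors = 16L,
      channels = channels,
      roi_map = .roi_channels,
      separation = separation
    ),
    class = "fnirs_montage"
  )
  validate_montage(m)
  m
}

#' Validate montage invariants
#'
#' Checks the structural invariants of a montage: exactly 48 channels with
#' unique ids, ROI channel lists that are pairwise disjoint subsets of the
#' channel ids, and exactly 39 ROI-labelled channels.
#'
#' @param m An `fnirs_montage`.
#' @return `m`, invisibly; errors if an invariant is violated.
#' @export
validate_montage <- function(m) {
  stopifnot(inherits(m, "fnirs_montage"))
  ch <- m$channels
  if (nrow(ch) != 48L) stop("montage must have exactly 48 channels")
  if (anyDuplicated(ch$id) || !all(ch$id %in% 1:48))
    stop("channel ids must be unique and in 1..48")
  all_roi <- unlist(m$roi_map, use.names = FALSE)
  if (anyDuplicated(all_roi)) stop("ROI channel lists must be pairwise disjoint")
  if (!all(all_roi %in% ch$id)) stop("ROI lists reference unknown channel ids")
  if (length(all_roi) != 39L)
    stop("expected 39 ROI-labelled channels, got ", length(all_roi))
  for (r in names(m$roi_map)) {
    if (!all(ch$roi[m$roi_map[[r]]] == r))
      stop("channel table roi column inconsistent with roi_map for ", r)
  }
  if (sum(ch$roi == "NONE") != 9L) stop("expected 9 unassigned channels")
  invisible(m)
}

#' Look up the ROI of a channel
#'
#' @param m An `fnirs_montage`.
#' @param id Channel id (1-based).
#' @return ROI label, `"NONE"` for unassigned channels.
#' @export
roi_of <- function(m, id) {
  stopifnot(all(id %in% m$channels$id))
  m$channels$roi[match(id, m$channels$id)]
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("fNIRS montage:", nrow(x$channels), "channels,",
      x$n_sources, "sources,", x$n_detectors, "detectors,",
      x$separation, "cm separation\n")
  for (r in names(x$roi_map))
    cat(sprintf("  %-4s %2d channels: %s\n", r, length(x$roi_map[[r]]),
                paste(x$roi_map[[r]], collapse = ", ")))
  cat("  unassigned:", sum(x$channels$roi == "NONE"), "channels\n")
  invisible(x)
}

#' Build the default walking-task paradigm
#'
#' The session clock starts at the onset of the first standing block (a
#' short preparatory period before it is not recorded on this clock). The
#' block sequence is: 60 s standing, 60 s freezing-induction walking, 30 s
#' standing rest, 60 s normal walking, 60 s standing, for a 270 s session.
#'
#' Analysis windows follow the epoching conventions used with this paradigm:
#' the resting baseline is 0--60 s, the freezing-induction window
#' 62.5--120 s and the normal-walking window 152.5--210 s. Activation
#' extraction additionally applies the rule "3--60 s after walk onset with a
#' 5 s pre-walk baseline" relative to the block boundaries (60 s and 150 s),
#' intersected with the stated analysis windows; see [segment_epochs()].
#'
#' All windows are half-open `[start, end)` in seconds; the sample index of
#' time `t` is `floor(t * fs)`.
#'
#' @return An object of class `fnirs_paradigm`.
#' @export
default_paradigm <- function() {
  blocks <- data.frame(
    label = c("stand", "freeze_walk", "rest", "normal_walk", "stand"),
    start = c(0, 60, 120, 150, 210),
    end   = c(60, 120, 150, 210, 270),
    stringsAsFactors = FALSE
  )
  p <- structure(
    list(
      blocks = blocks,
      analysis_windows = list(
        rest = c(0, 60),
        freeze_induction = c(62.5, 120),
        normal_walk = c(152.5, 210)
      ),
      walk_onsets = c(freeze_induction = 60, normal_walk = 150),
      baseline_window_s = 5.0,
      task_extract_window = c(3.0, 60.0)
    ),
    class = "fnirs_paradigm"
  )
  validate_paradigm(p)
  p
}

#' Validate paradigm invariants
#'
#' Blocks must be non-overlapping and monotonically increasing, and every
#' analysis window must lie inside the block sequence.
#'
#' @param p An `fnirs_paradigm`.
#' @return `p`, invisibly.
#' @export
validate_paradigm <- function(p) {
  stopifnot(inherits(p, "fnirs_paradigm"))
  b <- p$blocks
  if (any(b$end <= b$start)) stop("paradigm blocks must have end > start")
  if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
    stop("paradigm blocks must be non-overlapping and increasing")
  dur <- paradigm_duration(p)
  for (w in names(p$analysis_windows)) {
    win <- p$analysis_windows[[w]]
    if (win[1] < 0 || win[2] > dur || win[1] >= win[2])
      stop("analysis window '", w, "' outside recording [0, ", dur, "]")
  }
  invisible(p)
}

#' Total paradigm duration in seconds
#' @param p An `fnirs_paradigm`.
#' @return Duration in seconds.
#' @export
paradigm_duration <- function(p) max(p$blocks$end)

#' @export
print.fnirs_paradigm <- function(x, ...) {
  cat("fNIRS walking paradigm,", paradigm_duration(x), "s\n")
  for (i in seq_len(nrow(x$blocks)))
    cat(sprintf("  %3g-%3g s  %s\n", x$blocks$start[i], x$blocks$end[i],
                x$blocks$label[i]))
  cat("analysis windows:\n")
  for (w in names(x$analysis_windows))
    cat(sprintf("  %-16s [%g, %g) s\n", w, x$analysis_windows[[w]][1],
                x$analysis_windows[[w]][2]))
  invisible(x)
}

# Sample indices (1-based) of the half-open window [start, end) at rate
# fs: the samples whose times k/fs (k 0-based) lie inside the window,
# i.e. k from ceiling(start*fs) to ceiling(end*fs) - 1. A small epsilon
# guards the ceilings against floating-point representation of the
# products.
window_samples <- function(window, fs, n = NULL) {
  eps <- 1e-9
  i0 <- ceiling(window[1] * fs - eps)      # 0-based first sample
  i1 <- ceiling(window[2] * fs - eps)      # 0-based one-past-last
  idx <- seq.int(i0 + 1L, i1)
  if (!is.null(n) && (i1 > n || i0 < 0))
    stop("window [", window[1], ", ", window[2], ") outside recording")
  idx
}
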