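# Epoch segmentation, block averaging, baseline-corrected activation.

# Window arithmetic shared by the analysis and the simulator's calibration:
# walk onsets sit at the block boundaries (60 s, 150 s); the extraction rule
# "3-60 s after walk onset, 5 s pre-walk baseline" is applied relative to
# onset and intersected with the paradigm's stated analysis window.
.epoch_windows <- function(paradigm) {
  need <- c("rest", "freeze_induction", "normal_walk")
  missing <- setdiff(need, names(paradigm$analysis_windows))
  if (length(missing))
    stop("paradigm is missing analysis window(s): ",
         paste(missing, collapse = ", "))
  ex <- paradigm$task_extract_window
  bl <- paradigm$baseline_window_s
  out <- list(rest = list(task = paradigm$analysis_windows$rest,
                          baseline = NULL))
  for (cond in c("freeze_induction", "normal_walk")) {
    onset <- paradigm$walk_onsets[[cond]]
    win <- paradigm$analysis_windows[[cond]]
    task <- c(max(onset + ex[1], win[1]), min(onset + ex[2], win[2]))
    out[[cond]] <- list(task = task, baseline = c(onset - bl, onset))
  }
  out
}

#' Segment a hemoglobin series into condition epochs
#'
#' Builds the epoch set for the three conditions (rest,
#' freezing-induction walking, normal walking): task extraction windows of
#' 3--60 s after walk onset intersected with the paradigm's analysis
#' windows (giving `[63, 120)` and `[153, 210)` s under the default
#' paradigm), and 5-s pre-walk baselines (`[55, 60)`, `[145, 150)` s). The
#' rest epoch is the 0--60 s standing baseline with no separate baseline
#' window. All windows are half-open with sample index `floor(t * fs)`.
#'
#' @param hb An `hb_series` (or any list with `fs` and `data`).
#' @param paradigm An `fnirs_paradigm`.
#' @return Object of class `epoch_set`: per condition, the window times and
#'   extracted sample indices.
#' @export
segment_epochs <- function(hb, paradigm = hb$paradigm) {
  fs <- hb$fs
  n <- dim(hb$data)[1]
  win <- .epoch_windows(paradigm)
  eps <- lapply(names(win), function(cond) {
    w <- win[[cond]]
    task_idx <- window_samples(w$task, fs, n)
    base_idx <- if (!is.null(w$baseline)) window_samples(w$baseline, fs, n)
    list(condition = cond, task = w$task, baseline = w$baseline,
         task_idx = task_idx, baseline_idx = base_idx)
  })
  names(eps) <- names(win)
  structure(eps, class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set:\n")
  for (e in x) {
    cat(sprintf("  %-16s task [%g, %g) s (%d samples)", e$condition,
                e$task[1], e$task[2], length(e$task_idx)))
    if (!is.null(e$baseline))
      cat(sprintf(", baseline [%g, %g) s", e$baseline[1], e$baseline[2]))
    cat("\n")
  }
  invisible(x)
}

#' Block-average repeated trials
#'
#' Sample-wise mean across trials of the same condition; a single trial
#' passes through unchanged. All trials must have identical length.
#'
#' @param trials List of numeric vectors/matrices (one per trial).
#' @return The averaged trial.
#' @export
block_average <- function(trials) {
  stopifnot(is.list(trials), length(trials) >= 1)
  d1 <- if (is.null(dim(trials[[1]]))) length(trials[[1]]) else dim(trials[[1]])
  for (tr in trials) {
    d <- if (is.null(dim(tr))) length(tr) else dim(tr)
    if (!identical(d, d1)) stop("trial length mismatch in block_average")
  }
  Reduce(`+`, trials) / length(trials)
}

#' Per-channel activation value of one condition
#'
#' Mean HbO2 over the task extraction window minus mean over the baseline
#' window, per channel. Channels that are all-missing (QC-excluded)
#' propagate as `NA`.
#'
#' @param hb An `hb_series`.
#' @param condition `"freeze_induction"` or `"normal_walk"`.
#' @param epochs An `epoch_set`; computed from `hb` if omitted.
#' @return Named numeric vector (one value per channel, micromol/L).
#' @export
activation_value <- function(hb, condition = c("freeze_induction",
                                               "normal_walk"),
                             epochs = segment_epochs(hb)) {
  condition <- match.arg(condition)
  e <- epochs[[condition]]
  if (is.null(e$baseline_idx))
    stop("condition '", condition, "' has no baseline window")
  x <- hb$data[, , "HbO2"]
  val <- colMeans(x[e$task_idx, , drop = FALSE]) -
    colMeans(x[e$baseline_idx, , drop = FALSE])
  names(val) <- seq_along(val)
  val
}

#' Aggregate channel values to ROI means
#'
#' Unweighted arithmetic mean of each ROI's retained member channels;
#' missing (QC-excluded) channels are dropped from the mean, and channels
#' without an ROI label are ignored. An ROI with no retained channels
#' yields `NA` with a warning.
#'
#' @param channel_values Named numeric vector over channels (names are
#'   channel ids).
#' @param montage An `fnirs_montage`.
#' @return Named numeric vector over ROIs.
#' @export
roi_aggregate <- function(channel_values, montage = build_default_montage()) {
  out <- sapply(montage_rois(), function(r) {
    v <- channel_values[as.character(montage$roi_map[[r]])]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning("ROI ", r, " has no retained channels")
      return(NA_real_)
    }
    mean(v)
  })
  out
}
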