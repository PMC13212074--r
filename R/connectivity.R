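# Channel-wise Pearson functional connectivity and ROI aggregation.

#' Channel-by-channel functional connectivity matrix
#'
#' Pearson correlation of the HbO2 series between all channel pairs over
#' one condition's task extraction window. Rows/columns of QC-excluded
#' channels are `NA`; a retained channel with zero variance in the window
#' is also set to `NA` with a warning. Raw r is returned (no Fisher
#' transform, no thresholding; negative correlations are retained).
#'
#' @param hb An `hb_series`.
#' @param condition Condition whose extraction window to use.
#' @param epochs An `epoch_set`; computed from `hb` if omitted.
#' @return Object of class `fc_matrix`: 48 x 48 symmetric correlation
#'   matrix with attributes `subject_id`, `group`, `condition`,
#'   `valid` (logical per channel).
#' @export
fc_matrix <- function(hb, condition = c("freeze_induction", "normal_walk",
                                        "rest"),
                      epochs = segment_epochs(hb)) {
  condition <- match.arg(condition)
  e <- epochs[[condition]]
  if (length(e$task_idx) < 30)
    stop("connectivity window has fewer than 30 samples")
  x <- hb$data[e$task_idx, , "HbO2"]
  valid <- apply(is.finite(x), 2, all)
  sds <- rep(NA_real_, ncol(x))
  sds[valid] <- apply(x[, valid, drop = FALSE], 2, stats::sd)
  zerovar <- valid & (sds == 0)
  if (any(zerovar)) {
    warning("zero-variance channel(s) in window: ",
            paste(which(zerovar), collapse = ", "))
    valid <- valid & !zerovar
  }
  r <- matrix(NA_real_, ncol(x), ncol(x))
  r[valid, valid] <- stats::cor(x[, valid, drop = FALSE])
  structure(r, class = c("fc_matrix", "matrix"),
            subject_id = hb$subject_id, group = hb$group,
            condition = condition, valid = valid)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("FC matrix '%s' (%s, %s): %d x %d, %d valid channels\n",
              attr(x, "subject_id"), attr(x, "group"), attr(x, "condition"),
              nrow(x), ncol(x), sum(attr(x, "valid"))))
  off <- x[upper.tri(x)]
  cat(sprintf("  mean off-diagonal r = %.3f\n", mean(off, na.rm = TRUE)))
  invisible(x)
}

#' ROI-pair and intra-ROI connectivity
#'
#' Inter-ROI connectivity of a pair (A, B) is the mean of `r(i, j)` over
#' all member pairs `i` in A, `j` in B; intra-ROI connectivity is the mean
#' over unordered distinct pairs within the ROI (diagonal excluded).
#' Missing channels are dropped; a pair with no usable channel pair yields
#' `NA`.
#'
#' @param fc An `fc_matrix` (or plain matrix).
#' @param montage An `fnirs_montage`.
#' @return data.frame with columns `roi_a`, `roi_b`, `type`
#'   (`"inter"`/`"intra"`), `n_pairs`, `value`.
#' @export
roi_pair_fc <- function(fc, montage = build_default_montage()) {
  rois <- montage_rois()
  rows <- list()
  for (i in seq_along(rois)) for (j in i:length(rois)) {
    a <- rois[i]; b <- rois[j]
    ia <- montage$roi_map[[a]]; ib <- montage$roi_map[[b]]
    block <- fc[ia, ib, drop = FALSE]
    vals <- if (a == b) block[upper.tri(block)] else as.vector(block)
    vals <- vals[is.finite(vals)]
    rows[[length(rows) + 1L]] <- data.frame(
      roi_a = a, roi_b = b, type = if (a == b) "intra" else "inter",
      n_pairs = length(vals),
      value = if (length(vals)) mean(vals) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Channel pairs singled out for intervention comparisons
#'
#' The ten cortical channel pairs tracked across rhythmic-auditory-
#' stimulation conditions (temporal-prefrontal, temporal-premotor,
#' prefrontal-premotor, somatosensory couplings).
#'
#' @return data.frame with columns `ch_a`, `ch_b`.
#' @export
default_channel_pairs <- function() {
  data.frame(ch_a = c(1L, 1L, 3L, 4L, 5L, 11L, 16L, 17L, 23L, 31L),
             ch_b = c(27L, 31L, 35L, 43L, 42L, 27L, 27L, 41L, 27L, 35L))
}

#' Extract named channel-pair connectivity into a long table
#'
#' @param fc_list List of `fc_matrix` objects (one per subject/condition).
#' @param pairs data.frame with columns `ch_a`, `ch_b`; defaults to
#'   [default_channel_pairs()].
#' @param montage Montage used to label each pair with its ROI pair.
#' @return Long data.frame: `subject_id`, `group`, `condition`, `ch_a`,
#'   `ch_b`, `pair`, `roi_pair`, `r`. Empty `pairs` gives an empty table
#'   with the full header.
#' @export
channel_pair_table <- function(fc_list, pairs = default_channel_pairs(),
                               montage = build_default_montage()) {
  if (inherits(fc_list, "fc_matrix")) fc_list <- list(fc_list)
  empty <- data.frame(subject_id = character(0), group = character(0),
                      condition = character(0), ch_a = integer(0),
                      ch_b = integer(0), pair = character(0),
                      roi_pair = character(0), r = numeric(0))
  if (!nrow(pairs)) return(empty)
  if (!all(c(pairs$ch_a, pairs$ch_b) %in% montage$channels$id))
    stop("unknown channel id in pairs")
  out <- lapply(fc_list, function(fc) {
    data.frame(subject_id = attr(fc, "subject_id"),
               group = attr(fc, "group"),
               condition = attr(fc, "condition"),
               ch_a = pairs$ch_a, ch_b = pairs$ch_b,
               pair = paste0(pairs$ch_a, "-", pairs$ch_b),
               roi_pair = paste0(roi_of(montage, pairs$ch_a), "-",
                                 roi_of(montage, pairs$ch_b)),
               r = fc[cbind(pairs$ch_a, pairs$ch_b)])
  })
  rbind(empty, do.call(rbind, out))
}
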