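# Raw-intensity recording container and serialization.
#
# Serialization uses a plain long-format CSV (time_s, channel,
# wavelength_nm, intensity) preceded by '#key=value' header lines carrying
# the recording metadata, so a recording round-trips through a single text
# file. Montage and paradigm serialize to JSON.

#' Construct a raw-intensity recording
#'
#' @param data Numeric array `[time, channel, wavelength]` of detected light
#'   intensity in arbitrary units; all values must be strictly positive.
#' @param fs Sampling frequency in Hz.
#' @param subject_id Subject identifier.
#' @param group Group label, `"HC"` or `"PD_FOG"`.
#' @param wavelengths Wavelength pair in nm.
#' @param paradigm An `fnirs_paradigm`; the recording must cover it.
#' @return Object of class `fnirs_recording`.
#' @export
new_recording <- function(data, fs, subject_id, group = c("HC", "PD_FOG"),
                          wavelengths = c(730, 850),
                          paradigm = default_paradigm()) {
  group <- match.arg(group)
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(wavelengths))
  if (!all(is.finite(data)) || any(data <= 0))
    stop("intensities must be finite and strictly positive")
  if (dim(data)[1] / fs < paradigm_duration(paradigm))
    stop("recording shorter than paradigm (", dim(data)[1] / fs, " s < ",
         paradigm_duration(paradigm), " s)")
  structure(
    list(data = data, fs = fs, subject_id = subject_id, group = group,
         wavelengths = wavelengths, paradigm = paradigm),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "fNIRS recording '%s' (%s): %d channels x %d wavelengths (%s nm), %.1f s at %g Hz\n",
    x$subject_id, x$group, d[2], d[3],
    paste(x$wavelengths, collapse = "/"), d[1] / x$fs, x$fs))
  invisible(x)
}

#' Write a recording to long-format CSV
#'
#' @param rec An `fnirs_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fnirs_recording"))
  d <- dim(rec$data)
  hdr <- c("#fognirs_recording=1",
           paste0("#subject_id=", rec$subject_id),
           paste0("#group=", rec$group),
           paste0("#fs=", format(rec$fs, digits = 17)),
           paste0("#wavelengths=", paste(rec$wavelengths, collapse = ",")))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  long <- data.table::data.table(
    time_s = rep((seq_len(d[1]) - 1) / rec$fs, times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    wavelength_nm = rep(rec$wavelengths, each = d[1] * d[2]),
    # full shortest-round-trip precision so read(write(x)) is exact
    intensity = sprintf("%.17g", as.vector(rec$data))
  )
  data.table::fwrite(long, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a recording from long-format CSV
#'
#' Expects the format written by [write_recording()]: `#key=value` header
#' lines followed by a long CSV with columns `time_s`, `channel`,
#' `wavelength_nm`, `intensity`. Intensities must be strictly positive and
#' the implied sampling interval must agree with the `fs` header.
#'
#' @param path File path.
#' @param paradigm Paradigm the recording must cover.
#' @return An `fnirs_recording`.
#' @export
read_recording <- function(path, paradigm = default_paradigm()) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr_lines <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr_lines <- c(hdr_lines, ln)
  }
  close(con)
  if (!length(hdr_lines) || !startsWith(hdr_lines[1], "#fognirs_recording"))
    stop("malformed recording file (missing '#fognirs_recording' header): ", path)
  kv <- strsplit(sub("^#", "", hdr_lines), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  fs <- as.numeric(meta[["fs"]])
  wavelengths <- as.numeric(strsplit(meta[["wavelengths"]], ",")[[1]])

  long <- data.table::fread(path, skip = length(hdr_lines))
  need <- c("time_s", "channel", "wavelength_nm", "intensity")
  if (!all(need %in% names(long)))
    stop("malformed recording CSV, expected columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(long$intensity)) || any(long$intensity <= 0)) {
    bad <- which(!is.finite(long$intensity) | long$intensity <= 0)[1]
    stop("non-positive intensity at record ", bad, " of ", path)
  }
  chs <- sort(unique(long$channel))
  wls <- sort(unique(long$wavelength_nm))
  if (!isTRUE(all.equal(wls, sort(wavelengths))))
    stop("wavelengths in data disagree with header in ", path)
  ts <- sort(unique(long$time_s))
  if (length(ts) > 1) {
    dt <- stats::median(diff(ts))
    if (abs(dt - 1 / fs) > 1e-6)
      stop("sampling interval in data (", signif(dt, 6),
           " s) disagrees with header fs=", fs)
  }
  nt <- length(ts)
  data.table::setorder(long, wavelength_nm, channel, time_s)
  if (nrow(long) != nt * length(chs) * length(wls))
    stop("recording CSV is not a complete time x channel x wavelength grid")
  arr <- array(long$intensity, dim = c(nt, length(chs), length(wls)))
  new_recording(arr, fs = fs, subject_id = meta[["subject_id"]],
                group = meta[["group"]], wavelengths = wavelengths,
                paradigm = paradigm)
}

#' Serialize a montage or paradigm to JSON
#'
#' @param x An `fnirs_montage` or `fnirs_paradigm`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(x, path) {
  kind <- if (inherits(x, "fnirs_montage")) "montage"
          else if (inherits(x, "fnirs_paradigm")) "paradigm"
          else stop("x must be an fnirs_montage or fnirs_paradigm")
  obj <- unclass(x)
  # named atomic vectors would lose their names as JSON arrays
  if (!is.null(obj$walk_onsets)) obj$walk_onsets <- as.list(obj$walk_onsets)
  jsonlite::write_json(c(list(.kind = kind), obj), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a montage or paradigm from JSON
#'
#' @param path JSON file written by [write_design_json()].
#' @return The deserialized `fnirs_montage` or `fnirs_paradigm`.
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$.kind
  obj$.kind <- NULL
  if (identical(kind, "montage")) {
    obj$channels <- as.data.frame(obj$channels, stringsAsFactors = FALSE)
    obj$roi_map <- lapply(obj$roi_map, as.integer)
    obj$n_sources <- as.integer(obj$n_sources)
    obj$n_detectors <- as.integer(obj$n_detectors)
    m <- structure(obj, class = "fnirs_montage")
    validate_montage(m)
    m
  } else if (identical(kind, "paradigm")) {
    obj$blocks <- as.data.frame(obj$blocks, stringsAsFactors = FALSE)
    obj$analysis_windows <- lapply(obj$analysis_windows, as.numeric)
    obj$walk_onsets <- unlist(obj$walk_onsets)
    p <- structure(obj, class = "fnirs_paradigm")
    validate_paradigm(p)
    p
  } else stop("unrecognized design JSON: ", path)
}

#' Write result tables to CSV
#'
#' Writes each element of a named list of data frames to
#' `<out_dir>/<name>.csv`. Empty tables produce a header-only CSV.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    data.table::fwrite(as.data.frame(results[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
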