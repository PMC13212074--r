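# End-to-end orchestration: simulate (or load) -> preprocess -> activation
# -> connectivity -> group statistics -> tables.

#' Default pipeline configuration
#'
#' @param preset `"paper_like"` (group contrasts as in
#'   [default_activation_effects()] / [default_fc_structure()]) or
#'   `"null"` (no group contrast).
#' @param n_per_group Subjects per group.
#' @param seed Master seed.
#' @param out_dir Output directory for result tables, or `NULL` to skip
#'   writing.
#' @param fdr_q FDR level for channel-wise rejection sets.
#' @param qc_threshold,band,order,stdev_thresh,amp_thresh Stage parameters
#'   (CV %, bandpass Hz, filter order, motion thresholds).
#' @return Configuration list of class `run_config`.
#' @export
default_config <- function(preset = "paper_like", n_per_group = 28, seed = 1,
                           out_dir = NULL, fdr_q = 0.05, qc_threshold = 14,
                           band = c(0.01, 0.2), order = 3,
                           stdev_thresh = 6.0, amp_thresh = 0.5) {
  structure(list(preset = preset, n_per_group = n_per_group, seed = seed,
                 out_dir = out_dir, fdr_q = fdr_q,
                 qc_threshold = qc_threshold, band = band, order = order,
                 stdev_thresh = stdev_thresh, amp_thresh = amp_thresh),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [default_config()] defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(y)) cfg[[k]] <- y[[k]]
  cfg
}

# measurements for one preprocessed subject
.measure_subject <- function(hb, montage, pairs) {
  eps <- segment_epochs(hb)
  act <- list(); fc_roi <- list(); fc_ch <- list()
  for (cond in c("freeze_induction", "normal_walk")) {
    ch_val <- activation_value(hb, cond, eps)
    roi_val <- suppressWarnings(roi_aggregate(ch_val, montage))
    act[[cond]] <- list(channel = ch_val, roi = roi_val)
    fc <- suppressWarnings(fc_matrix(hb, cond, eps))
    fc_roi[[cond]] <- roi_pair_fc(fc, montage)
    fc_ch[[cond]] <- channel_pair_table(fc, pairs, montage)
  }
  list(subject_id = hb$subject_id, group = hb$group, activation = act,
       fc_roi = fc_roi, fc_ch = fc_ch, n_retained = sum(hb$qc$retained))
}

#' Simulate and analyse a cohort, subject by subject
#'
#' Streams the full chain (simulate -> preprocess -> activation ->
#' connectivity) over every subject of a cohort without retaining the raw
#' recordings, and collects per-subject measures.
#'
#' @param spec A [cohort_spec()].
#' @param config A `run_config` controlling stage parameters.
#' @param fs Sampling rate.
#' @param montage,paradigm Montage and paradigm.
#' @return List of class `cohort_measures`: `activation` (long data.frame),
#'   `fc` (long data.frame over ROI pairs), `fc_channels` (long data.frame
#'   over tracked channel pairs), `gait`, `spec`.
#' @export
run_cohort <- function(spec, config = default_config(), fs = 11,
                       montage = build_default_montage(),
                       paradigm = default_paradigm()) {
  set.seed(spec$seed)
  n <- spec$n_per_group
  groups <- rep(c("HC", "PD_FOG"), each = n)
  ids <- c(sprintf("HC%02d", seq_len(n)), sprintf("PD%02d", seq_len(n)))
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
  gait <- simulate_gait(spec, ids, groups)
  pairs <- default_channel_pairs()
  fpar <- filter_params(band = config$band, order = config$order)
  mpar <- motion_params(stdev_thresh = config$stdev_thresh,
                        amp_thresh = config$amp_thresh)
  act_rows <- list(); fc_rows <- list(); fcch_rows <- list()
  for (i in seq_along(ids)) {
    rec <- simulate_session(spec, ids[i], groups[i], seed = seeds[i],
                            fs = fs, montage = montage, paradigm = paradigm)
    hb <- preprocess(rec, qc_threshold = config$qc_threshold, motion = mpar,
                     filter = fpar)
    m <- .measure_subject(hb, montage, pairs)
    for (cond in names(m$activation)) {
      a <- m$activation[[cond]]
      act_rows[[length(act_rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], condition = cond,
        level = c(rep("channel", length(a$channel)), rep("roi", length(a$roi))),
        label = c(names(a$channel), names(a$roi)),
        value = c(unname(a$channel), unname(a$roi)))
      fr <- m$fc_roi[[cond]]
      fc_rows[[length(fc_rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], condition = cond,
        type = fr$type, label = paste0(fr$roi_a, "-", fr$roi_b),
        value = fr$value)
      fcch_rows[[length(fcch_rows) + 1L]] <- m$fc_ch[[cond]]
    }
  }
  structure(list(activation = do.call(rbind, act_rows),
                 fc = do.call(rbind, fc_rows),
                 fc_channels = do.call(rbind, fcch_rows),
                 gait = gait, spec = spec, config = config),
            class = "cohort_measures")
}

# two-group summary table over a long measure data.frame split by `label`
.group_table <- function(df, fdr_q = 0.05) {
  labs <- unique(df$label)
  rows <- lapply(labs, function(lb) {
    x <- df$value[df$label == lb & df$group == "HC"]
    y <- df$value[df$label == lb & df$group == "PD_FOG"]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(label = lb, hc_mean = NA, hc_sd = NA, pd_mean = NA,
                        pd_sd = NA, statistic = NA, df = NA, effect = NA,
                        p = NA))
    r <- ttest_from_summary(mean(x), stats::sd(x), length(x),
                            mean(y), stats::sd(y), length(y))
    data.frame(label = lb, hc_mean = mean(x), hc_sd = stats::sd(x),
               pd_mean = mean(y), pd_sd = stats::sd(y),
               statistic = r$statistic, df = r$df, effect = r$effect,
               p = r$p)
  })
  tab <- do.call(rbind, rows)
  adj <- bh_fdr(tab$p, fdr_q)
  tab$p_adjusted <- adj$p_adjusted
  tab$significant <- adj$reject
  tab
}

#' Group-statistics tables for a cohort
#'
#' Builds the group-comparison tables from per-subject measures: ROI and
#' channel-wise activation contrasts (freezing-induction period, healthy
#' controls vs patients, pooled t with Cohen's d and BH-FDR across
#' channels), inter-ROI and intra-ROI connectivity contrasts, and gait
#' comparisons.
#'
#' @param measures A `cohort_measures` from [run_cohort()].
#' @param condition Condition for the group contrasts.
#' @return Named list of data.frames: `activation_roi`,
#'   `activation_channel`, `fc_inter`, `fc_intra`, `fc_channel_pairs`,
#'   `gait_freeze_vs_normal`, `gait_interventions`.
#' @export
cohort_group_stats <- function(measures, condition = "freeze_induction") {
  q <- measures$config$fdr_q
  act <- measures$activation[measures$activation$condition == condition, ]
  fc <- measures$fc[measures$fc$condition == condition, ]
  fcc <- measures$fc_channels[measures$fc_channels$condition == condition, ]
  fcc$label <- fcc$pair
  fcc$value <- fcc$r
  list(
    activation_roi = .group_table(act[act$level == "roi", ], q),
    activation_channel = .group_table(act[act$level == "channel", ], q),
    fc_inter = .group_table(fc[fc$type == "inter", ], q),
    fc_intra = .group_table(fc[fc$type == "intra", ], q),
    fc_channel_pairs = .group_table(fcc, q),
    gait_freeze_vs_normal = gait_compare(measures$gait, "freeze_vs_normal"),
    gait_interventions = gait_compare(measures$gait, "interventions")
  )
}

#' Run the full pipeline
#'
#' Simulates a cohort under the configured preset, runs every analysis
#' stage, computes the group-statistics tables, and (optionally) writes
#' them as CSVs together with a machine-readable run manifest. A completed
#' run is a pure function of the configuration and seed.
#'
#' @param config A `run_config` (see [default_config()]), or a path to a
#'   YAML file of overrides.
#' @return List with `measures` (per-subject values), `tables` (group
#'   statistics), `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  spec <- cohort_spec(n_per_group = config$n_per_group, seed = config$seed,
                      preset = config$preset)
  measures <- run_cohort(spec, config)
  tables <- cohort_group_stats(measures)
  tf <- tempfile()
  saveRDS(config, tf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fognirs")),
    r_version = R.version.string,
    seed = config$seed,
    preset = config$preset,
    n_per_group = config$n_per_group,
    config_md5 = unname(tools::md5sum(tf)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  unlink(tf)
  if (!is.null(config$out_dir)) {
    write_tables(tables, config$out_dir)
    data.table::fwrite(measures$activation,
                       file.path(config$out_dir, "subject_activation.csv"))
    data.table::fwrite(measures$fc,
                       file.path(config$out_dir, "subject_fc.csv"))
    data.table::fwrite(measures$gait,
                       file.path(config$out_dir, "gait.csv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(measures = measures, tables = tables, manifest = manifest)
}
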