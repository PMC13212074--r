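# Group-statistics layer: normality gating, two-sample parametric and
# nonparametric tests, summary-statistic t with pooled-SD Cohen's d,
# one-way repeated-measures ANOVA with partial eta^2 and LSD post-hoc,
# Benjamini-Hochberg FDR, and gait comparisons.

#' Construct a statistical-test result
#'
#' @param statistic Test statistic value.
#' @param df Degrees of freedom (scalar or pair).
#' @param p Two-sided p value.
#' @param effect Effect size.
#' @param effect_kind One of `"cohens_d"`, `"partial_eta_sq"`,
#'   `"rank_biserial"`, `"none"`.
#' @param test_name Identifier of the test.
#' @param p_adjusted Optional FDR-adjusted p.
#' @param extra Optional list of test-specific extras (e.g. post-hoc table).
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(statistic, df, p, effect = NA_real_,
                        effect_kind = "none", test_name, p_adjusted = NA_real_,
                        extra = list()) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  if (!is.na(p_adjusted) && !is.na(p) && p_adjusted < p - 1e-12)
    stop("adjusted p cannot be smaller than raw p")
  structure(list(statistic = statistic, df = df, p = p, effect = effect,
                 effect_kind = effect_kind, test_name = test_name,
                 p_adjusted = p_adjusted, extra = extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g", x$test_name,
              x$statistic, paste(signif(x$df, 4), collapse = ", "), x$p))
  if (!is.na(x$effect)) cat(sprintf(", %s = %.3g", x$effect_kind, x$effect))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p_adj = %.4g", x$p_adjusted))
  cat("\n")
  invisible(x)
}

#' Route samples to a parametric or nonparametric test
#'
#' Shapiro-Wilk normality test per group at level `alpha`; the parametric
#' route is taken iff every group passes. Groups with fewer than 3
#' observations or zero variance route to nonparametric with a warning.
#'
#' @param samples List of numeric vectors (one per group).
#' @param alpha Gate level. Default 0.05.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1)
  for (x in samples) {
    x <- x[is.finite(x)]
    if (length(x) < 3) {
      warning("group with n < 3; routing to nonparametric")
      return("nonparametric")
    }
    if (stats::sd(x) == 0) {
      warning("zero-variance group; routing to nonparametric")
      return("nonparametric")
    }
    if (stats::shapiro.test(x)$p.value < alpha) return("nonparametric")
  }
  "parametric"
}

#' Independent-samples t-test from group summaries
#'
#' Pooled-variance Student t from `(mean, sd, n)` triples:
#' `t = (m_a - m_b) / sqrt(s_p^2 (1/n_a + 1/n_b))` with
#' `s_p^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)` and
#' `df = n_a + n_b - 2`. Cohen's d uses the pooled SD with the sign
#' convention `d = (m_b - m_a) / s_p` (positive when group b exceeds
#' group a, matching a negative t).
#'
#' @param mean_a,sd_a,n_a Summary of group a.
#' @param mean_b,sd_b,n_b Summary of group b.
#' @return A `stat_result` (`test_name = "t_pooled_summary"`).
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b)
      return(stat_result(0, df, 1, 0, "cohens_d", "t_pooled_summary"))
    return(stat_result(sign(mean_a - mean_b) * Inf, df, 0,
                       sign(mean_b - mean_a) * Inf, "cohens_d",
                       "t_pooled_summary",
                       extra = list(degenerate = "zero pooled variance")))
  }
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tval <- (mean_a - mean_b) / se
  d <- (mean_b - mean_a) / sqrt(sp2)
  stat_result(tval, df, 2 * stats::pt(-abs(tval), df), d, "cohens_d",
              "t_pooled_summary")
}

#' Independent-samples t-test from raw samples
#'
#' Identical to [ttest_from_summary()] applied to the sample means, SDs
#' and sizes (pooled-variance Student t by default; Welch via
#' `welch = TRUE`).
#'
#' @param x,y Numeric samples.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return A `stat_result`.
#' @export
ttest_from_samples <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (!welch) {
    res <- ttest_from_summary(mean(x), stats::sd(x), length(x),
                              mean(y), stats::sd(y), length(y))
    res$test_name <- "t_pooled"
    return(res)
  }
  ht <- stats::t.test(x, y)
  sp <- sqrt((stats::var(x) + stats::var(y)) / 2)
  stat_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              (mean(y) - mean(x)) / sp, "cohens_d", "t_welch")
}

#' Mann-Whitney U test
#'
#' Exact U statistic (`U(x, y)` counts pairs with x > y, ties counted
#' half) with normal-approximation p including tie correction. The effect
#' is the rank-biserial correlation `1 - 2U/(n_x n_y)`.
#'
#' @param x,y Numeric samples.
#' @return A `stat_result` (`statistic` is U).
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (length(unique(c(x, y))) == 1) {
    warning("all observations tied; p = 1")
    return(stat_result(length(x) * length(y) / 2, NA_real_, 1, 0,
                       "rank_biserial", "mann_whitney"))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  U <- unname(ht$statistic)
  stat_result(U, NA_real_, ht$p.value,
              1 - 2 * U / (length(x) * length(y)), "rank_biserial",
              "mann_whitney")
}

#' Kruskal-Wallis H test
#'
#' @param groups List of numeric samples.
#' @return A `stat_result` (`statistic` is tie-corrected H, chi-squared
#'   approximation p).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(unique(unlist(groups))) == 1) {
    warning("all observations tied; p = 1")
    return(stat_result(0, length(groups) - 1, 1, NA_real_, "none",
                       "kruskal_wallis"))
  }
  ht <- stats::kruskal.test(groups)
  stat_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              NA_real_, "none", "kruskal_wallis")
}

#' One-way repeated-measures ANOVA with LSD post-hoc
#'
#' Subjects-by-conditions design with subject as blocking factor:
#' `F = MS_condition / MS_error` on `(k-1, (k-1)(n-1))` degrees of
#' freedom, partial eta^2 `= SS_cond / (SS_cond + SS_error)`, and Fisher's
#' LSD post-hoc (uncorrected pairwise paired t-tests between all condition
#' pairs).
#'
#' @param responses `n_subjects x k_conditions` numeric matrix (complete
#'   cases only).
#' @param conditions Condition labels; default the matrix column names.
#' @return A `stat_result` (`effect_kind = "partial_eta_sq"`) whose
#'   `extra$posthoc` is a data.frame of LSD comparisons.
#' @export
rm_anova <- function(responses, conditions = colnames(responses)) {
  responses <- as.matrix(responses)
  n <- nrow(responses); k <- ncol(responses)
  stopifnot(k >= 2, n >= 3)
  if (anyNA(responses)) {
    bad <- which(apply(is.na(responses), 1, any))
    stop("incomplete repeated-measures design; missing cells for subject(s) ",
         paste(bad, collapse = ", "))
  }
  if (is.null(conditions)) conditions <- paste0("C", seq_len(k))
  y <- as.vector(responses)
  subj <- factor(rep(seq_len(n), times = k))
  cond <- factor(rep(conditions, each = n), levels = conditions)
  aovtab <- stats::anova(stats::lm(y ~ subj + cond))
  ss_cond <- aovtab["cond", "Sum Sq"]
  ss_err <- aovtab["Residuals", "Sum Sq"]
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  # degenerate designs: compare sums of squares on a relative scale
  eps <- 1e-12 * (sum(y^2) + 1)
  if (ss_cond < eps) ss_cond <- 0
  if (ss_err < eps) ss_err <- 0
  ms_err <- ss_err / df2
  Fval <- if (ms_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else (ss_cond / df1) / ms_err
  p <- if (is.infinite(Fval)) 0 else stats::pf(Fval, df1, df2,
                                               lower.tail = FALSE)
  peta <- if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err)
  ph <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- responses[, i] - responses[, j]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = n - 1),
                 p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- stats::t.test(d)
    ph[[length(ph) + 1L]] <- data.frame(
      a = conditions[i], b = conditions[j],
      mean_diff = mean(d), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value)
  }
  stat_result(Fval, c(df1, df2), p, peta, "partial_eta_sq", "rm_anova",
              extra = list(posthoc = do.call(rbind, ph),
                           ss = c(cond = ss_cond, error = ss_err)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values with enforced monotonicity (via
#' [stats::p.adjust()]) and the rejection set at level `q`.
#'
#' @param p Vector of p values in `[0, 1]`.
#' @param q FDR level for the rejection set. Default 0.05.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Normality-gated two-group comparison
#'
#' Applies the package's test-selection rule: Shapiro-Wilk on both groups;
#' pooled t-test if both pass, Mann-Whitney U otherwise.
#'
#' @param x,y Numeric samples.
#' @param alpha Gate level.
#' @param gate If `FALSE`, always use the t-test.
#' @return A `stat_result`.
#' @export
group_compare <- function(x, y, alpha = 0.05, gate = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  route <- if (gate) suppressWarnings(normality_gate(list(x, y), alpha))
           else "parametric"
  if (route == "parametric") ttest_from_samples(x, y) else mann_whitney(x, y)
}

#' Gait-parameter comparisons
#'
#' Two contrasts over simulated or recorded gait tables:
#' `"freeze_vs_normal"` compares each gait parameter between the
#' freezing-induction and normal-walking conditions within subject (paired
#' t if the differences pass the normality gate, Wilcoxon signed-rank
#' otherwise); `"interventions"` runs a one-way repeated-measures ANOVA
#' across the four freezing-period intervention conditions (NONE, RAS_B,
#' RAS_M, RAS_I). Freezing-episode counts are integer-valued and compared
#' nonparametrically.
#'
#' @param gait Gait data.frame as produced by [simulate_gait()].
#' @param contrast `"freeze_vs_normal"` or `"interventions"`.
#' @param group Group to analyse. Default `"PD_FOG"`.
#' @param alpha Normality-gate level.
#' @return data.frame with one row per gait parameter: test name,
#'   statistic, df, p, effect.
#' @export
gait_compare <- function(gait, contrast = c("freeze_vs_normal",
                                            "interventions"),
                         group = "PD_FOG", alpha = 0.05) {
  contrast <- match.arg(contrast)
  g <- gait[gait$group == group, ]
  params <- c("cadence", "stride_length", "velocity", "swing_width",
              "foot_progression_angle", "fog_count")
  params <- intersect(params, names(g))
  rows <- list()
  if (contrast == "freeze_vs_normal") {
    a <- g[g$condition == "freeze_induction" & g$intervention == "NONE", ]
    b <- g[g$condition == "normal_walk" & g$intervention == "NONE", ]
    common <- intersect(a$subject_id, b$subject_id)
    if (!setequal(a$subject_id, b$subject_id))
      stop("unmatched subjects across conditions")
    a <- a[match(common, a$subject_id), ]
    b <- b[match(common, b$subject_id), ]
    for (p in params) {
      d <- a[[p]] - b[[p]]
      force_np <- p == "fog_count"
      route <- if (force_np) "nonparametric"
               else suppressWarnings(normality_gate(list(d), alpha))
      if (route == "parametric") {
        tt <- stats::t.test(d)
        res <- stat_result(unname(tt$statistic), unname(tt$parameter),
                           tt$p.value, mean(d) / stats::sd(d), "cohens_d",
                           "paired_t")
      } else if (stats::sd(d) == 0) {
        res <- stat_result(0, NA_real_, 1, 0, "none", "wilcoxon_signed_rank")
      } else {
        wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE))
        res <- stat_result(unname(wt$statistic), NA_real_, wt$p.value,
                           NA_real_, "none", "wilcoxon_signed_rank")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, test = res$test_name, statistic = res$statistic,
        df = res$df[1], p = res$p, effect = res$effect)
    }
  } else {
    levels_i <- c("NONE", "RAS_B", "RAS_M", "RAS_I")
    fr <- g[g$condition == "freeze_induction" &
              g$intervention %in% levels_i, ]
    subs <- sort(unique(fr$subject_id))
    for (p in params) {
      m <- sapply(levels_i, function(iv) {
        x <- fr[fr$intervention == iv, ]
        x[[p]][match(subs, x$subject_id)]
      })
      if (anyNA(m)) stop("unmatched subjects across interventions")
      if (p == "fog_count") {
        res <- kruskal_wallis(lapply(seq_len(ncol(m)), function(j) m[, j]))
      } else {
        res <- rm_anova(m, levels_i)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, test = res$test_name, statistic = res$statistic,
        df = res$df[1], p = res$p, effect = res$effect)
    }
  }
  do.call(rbind, rows)
}
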