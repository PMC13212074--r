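test_that("summary-statistic t and Cohen's d match hand-checked values", {
  # hand arithmetic: groups (0, 1, 2) and (1, 1, 2)
  r <- ttest_from_summary(0, 1, 2, 1, 1, 2)
  expect_equal(r$statistic, -1.0, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$effect, 1.0, tolerance = 1e-12)
  # identical summaries
  r0 <- ttest_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect, 0)
  # degenerate zero-variance cases
  expect_equal(ttest_from_summary(1, 0, 5, 1, 0, 5)$statistic, 0)
  inf <- ttest_from_summary(1, 0, 5, 2, 0, 5)
  expect_true(is.infinite(inf$statistic))
})

test_that("sample and summary t-tests agree exactly, matching stats::t.test", {
  set.seed(81)
  for (k in 1:5) {
    x <- stats::rnorm(20 + k, mean = 0.3); y <- stats::rnorm(25 - k)
    rs <- ttest_from_samples(x, y)
    rm <- ttest_from_summary(mean(x), stats::sd(x), length(x),
                             mean(y), stats::sd(y), length(y))
    expect_equal(rs$statistic, rm$statistic, tolerance = 1e-12)
    expect_equal(rs$p, rm$p, tolerance = 1e-12)
    ht <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(rs$statistic, unname(ht$statistic), tolerance = 1e-10)
    expect_equal(rs$p, ht$p.value, tolerance = 1e-10)
    # equal-n algebraic identity: t = (m1 - m2) / sqrt((s1^2 + s2^2) / n)
    z <- stats::rnorm(20 + k)
    re <- ttest_from_samples(x, z)
    tid <- (mean(x) - mean(z)) /
      sqrt((stats::var(x) + stats::var(z)) / length(x))
    expect_equal(re$statistic, tid, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U matches enumeration and its pairing identity", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  set.seed(82)
  for (k in 1:10) {
    x <- sample(1:8, 12, replace = TRUE)   # ties included
    y <- sample(3:10, 9, replace = TRUE)
    u1 <- mann_whitney(x, y)$statistic
    u2 <- mann_whitney(y, x)$statistic
    expect_equal(u1 + u2, length(x) * length(y))
    # enumeration oracle with half-counted ties
    uo <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(u1, uo)
    expect_equal(mann_whitney(x, y)$p,
                 suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                     correct = FALSE))$p.value)
  }
  expect_warning(rt <- mann_whitney(rep(2, 5), rep(2, 6)), "tied")
  expect_equal(rt$p, 1)
})

test_that("Kruskal-Wallis wraps the tie-corrected H statistic", {
  set.seed(83)
  g <- list(stats::rnorm(10), stats::rnorm(12, 1), stats::rnorm(8))
  r <- kruskal_wallis(g)
  ht <- stats::kruskal.test(g)
  expect_equal(r$statistic, unname(ht$statistic))
  expect_equal(r$p, ht$p.value)
  i <- list(c(1, 2, 3), c(1, 2, 3))
  expect_gt(kruskal_wallis(i)$p, 0.9)
})

test_that("repeated-measures ANOVA matches a brute-force SS oracle", {
  rm_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    gm <- mean(m)
    ss_cond <- n * sum((colMeans(m) - gm)^2)
    ss_subj <- k * sum((rowMeans(m) - gm)^2)
    ss_tot <- sum((m - gm)^2)
    ss_err <- ss_tot - ss_cond - ss_subj
    f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
    list(F = f, peta = ss_cond / (ss_cond + ss_err))
  }
  set.seed(84)
  for (k in 1:5) {
    m <- matrix(stats::rnorm(6 * 4, mean = rep(c(0, 0.5, 1, 0.2), each = 6)),
                6, 4, dimnames = list(NULL, paste0("C", 1:4)))
    r <- rm_anova(m)
    o <- rm_oracle(m)
    expect_equal(r$statistic, o$F, tolerance = 1e-9)
    expect_equal(r$effect, o$peta, tolerance = 1e-9)
    expect_equal(r$df, c(3, 15))
    expect_gte(r$effect, 0); expect_lte(r$effect, 1)
    expect_equal(nrow(r$extra$posthoc), 6L)
  }
})

test_that("rm_anova reduces to the paired t-test at two conditions", {
  set.seed(85)
  m <- matrix(stats::rnorm(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  r <- rm_anova(m)
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)
  # toy design with a constant condition difference (perfect-fit ANOVA
  # warnings from the underlying lm are expected here)
  toy <- cbind(A = c(1, 2, 3), B = c(2, 3, 4))
  rt <- suppressWarnings(rm_anova(toy))
  expect_true(is.infinite(rt$statistic) || rt$statistic > 1e10)
  expect_equal(rt$p, 0)
  # all-identical conditions
  same <- matrix(rep(c(1, 2, 3), 3), 3, 3)
  r0 <- suppressWarnings(rm_anova(same, conditions = c("A", "B", "C")))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect, 0)
  # incomplete designs are refused with the subject named
  holed <- m; holed[3, 2] <- NA
  expect_error(rm_anova(holed), "3")
})

test_that("BH adjustment matches the hand step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$p_adjusted,
               rep(0.04, 4))
  set.seed(86)
  for (k in 1:50) {
    p <- stats::runif(sample(2:12, 1))^2
    r <- bh_fdr(p)
    expect_equal(r$p_adjusted, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(r$p_adjusted >= p - 1e-12))
    s <- order(p)
    expect_true(all(diff(r$p_adjusted[s]) >= -1e-12))
  }
})

test_that("the normality gate routes clean and skewed data correctly", {
  set.seed(87)
  par_hits <- mean(vapply(1:20, function(i)
    normality_gate(list(stats::rnorm(80), stats::rnorm(80))) == "parametric",
    logical(1)))
  expect_gte(par_hits, 0.8)
  np_hits <- mean(vapply(1:20, function(i)
    normality_gate(list(exp(stats::rnorm(50, sd = 1)))) == "nonparametric",
    logical(1)))
  expect_gte(np_hits, 0.9)
  expect_warning(r <- normality_gate(list(rep(1, 10))), "zero-variance")
  expect_equal(r, "nonparametric")
  expect_warning(r2 <- normality_gate(list(c(1, 2))), "n < 3")
  expect_equal(r2, "nonparametric")
})

test_that("gait comparisons pair subjects and route count data", {
  spec <- cohort_spec(seed = 9)
  set.seed(9)
  gait <- simulate_gait(spec, sprintf("P%02d", 1:28), rep("PD_FOG", 28))
  tab <- gait_compare(gait, "freeze_vs_normal")
  expect_equal(nrow(tab), 6L)
  expect_true(tab$test[tab$parameter == "fog_count"] %in%
                c("wilcoxon_signed_rank"))
  # a strong paired velocity deficit is detected
  expect_lt(tab$p[tab$parameter == "velocity"], 0.01)
  tab2 <- gait_compare(gait, "interventions")
  expect_equal(tab2$test[tab2$parameter == "fog_count"], "kruskal_wallis")
  expect_true(all(tab2$test[tab2$parameter != "fog_count"] == "rm_anova"))
  # unmatched subjects abort
  broken <- gait[-1, ]
  expect_error(gait_compare(broken, "freeze_vs_normal"), "unmatched")
  # identical paired values give the degenerate zero test
  g0 <- gait
  g0[g0$condition == "normal_walk", c("cadence", "stride_length", "velocity",
                                      "swing_width",
                                      "foot_progression_angle")] <-
    g0[g0$condition == "freeze_induction" & g0$intervention == "NONE",
       c("cadence", "stride_length", "velocity", "swing_width",
         "foot_progression_angle")]
  t0 <- gait_compare(g0, "freeze_vs_normal")
  expect_equal(t0$statistic[t0$parameter == "velocity"], 0)
})
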