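test_that("FC matrices satisfy the basic correlation identities", {
  set.seed(71)
  n <- 2970
  base <- stats::rnorm(n)
  hbo <- matrix(stats::rnorm(n * 48), n, 48)
  hbo[, 2] <- hbo[, 1]          # identical
  hbo[, 3] <- -hbo[, 1]         # anti-correlated
  fc <- fc_matrix(make_hb(hbo), "freeze_induction")
  expect_equal(unname(diag(fc)[1]), 1)
  expect_equal(fc[1, 2], 1, tolerance = 1e-12)
  expect_equal(fc[1, 3], -1, tolerance = 1e-12)
  expect_true(all(abs(fc[is.finite(fc)]) <= 1 + 1e-12))
  expect_equal(unname(fc), unname(t(fc)))
})

test_that("zero-variance channels drop out with a warning", {
  set.seed(72)
  hbo <- matrix(stats::rnorm(2970 * 48), 2970, 48)
  hbo[, 5] <- 2.0
  expect_warning(fc <- fc_matrix(make_hb(hbo), "freeze_induction"),
                 "zero-variance")
  expect_true(all(is.na(fc[5, ])))
  expect_true(all(is.na(fc[, 5])))
  expect_false(attr(fc, "valid")[5])
})

test_that("FC is channel-order equivariant", {
  set.seed(73)
  hbo <- matrix(stats::rnorm(2970 * 48), 2970, 48)
  fc <- fc_matrix(make_hb(hbo), "freeze_induction")
  perm <- sample(48)
  fcp <- fc_matrix(make_hb(hbo[, perm]), "freeze_induction")
  expect_equal(matrix(fcp, 48, 48), matrix(fc[perm, perm], 48, 48),
               tolerance = 1e-12)
})

test_that("ROI aggregation of connectivity matches a pair-enumeration oracle", {
  m <- build_default_montage()
  # constant off-diagonal: every inter and intra value equals that constant
  fc0 <- matrix(0.2, 48, 48); diag(fc0) <- 1
  tab0 <- roi_pair_fc(fc0, m)
  expect_true(all(abs(tab0$value - 0.2) < 1e-12))
  expect_equal(nrow(tab0), 15L)
  expect_equal(sum(tab0$type == "inter"), 10L)
  expect_equal(sum(tab0$type == "intra"), 5L)
  # random matrix: brute-force enumeration oracle
  set.seed(74)
  r <- stats::cor(matrix(stats::rnorm(500 * 48), 500, 48))
  tab <- roi_pair_fc(r, m)
  oracle_inter <- function(A, B) {
    vals <- c()
    for (i in m$roi_map[[A]]) for (j in m$roi_map[[B]]) vals <- c(vals, r[i, j])
    mean(vals)
  }
  oracle_intra <- function(A) {
    ch <- m$roi_map[[A]]
    vals <- c()
    for (i in seq_along(ch)) for (j in seq_along(ch))
      if (i < j) vals <- c(vals, r[ch[i], ch[j]])
    mean(vals)
  }
  pick <- function(a, b) tab$value[tab$roi_a == a & tab$roi_b == b]
  expect_equal(pick("PFC", "TLC"), oracle_inter("PFC", "TLC"))
  expect_equal(pick("S1", "TLC"), oracle_inter("S1", "TLC"))
  expect_equal(pick("PFC", "PFC"), oracle_intra("PFC"))
  expect_equal(pick("S1", "S1"), oracle_intra("S1"))
  # intra-M1 is the single channel pair (37, 44)
  expect_equal(pick("M1", "M1"), r[37, 44])
  expect_equal(tab$n_pairs[tab$roi_a == "M1" & tab$roi_b == "M1"], 1L)
})

test_that("channel-pair tables carry montage labels and propagate values", {
  set.seed(75)
  hbo <- matrix(stats::rnorm(2970 * 48), 2970, 48)
  fc <- fc_matrix(make_hb(hbo), "freeze_induction")
  tab <- channel_pair_table(fc)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$roi_pair[tab$pair == "1-27"], "TLC-PFC")
  expect_equal(tab$r[tab$pair == "1-27"], fc[1, 27])
  # self-pair gives the constant 1 column
  self <- channel_pair_table(fc, data.frame(ch_a = 3L, ch_b = 3L))
  expect_equal(self$r, 1)
  # empty pair list: empty table with the full header
  e <- channel_pair_table(fc, data.frame(ch_a = integer(0), ch_b = integer(0)))
  expect_equal(nrow(e), 0L)
  expect_true(all(c("subject_id", "pair", "roi_pair", "r") %in% names(e)))
  expect_error(channel_pair_table(fc, data.frame(ch_a = 1L, ch_b = 99L)),
               "unknown channel")
})

test_that("windowed sample correlation concentrates around the latent value", {
  # two channels share a latent signal mixed for rho = 0.5; with ~630
  # near-independent samples the sample r stays within [0.3, 0.7]
  w <- sqrt(0.5)
  rs <- vapply(1:50, function(s) {
    set.seed(600 + s)
    z <- stats::rnorm(632)
    x <- w * z + sqrt(1 - w^2) * stats::rnorm(632)
    y <- w * z + sqrt(1 - w^2) * stats::rnorm(632)
    stats::cor(x, y)
  }, numeric(1))
  expect_true(all(rs > 0.3 & rs < 0.7))
  expect_equal(mean(rs), 0.5, tolerance = 0.03)
})
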