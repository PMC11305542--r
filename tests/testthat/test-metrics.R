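test_that("confusion counts match a per-pixel double loop", {
  set.seed(11)
  p <- matrix(runif(256) > 0.5, 16, 16)
  t <- matrix(runif(256) > 0.5, 16, 16)
  e <- matrix(runif(256) > 0.8, 16, 16)
  got <- confusion(p, t, e)
  want <- bf_confusion(p, t, e)
  expect_equal(got$TP, want$TP)
  expect_equal(got$FP, want$FP)
  expect_equal(got$FN, want$FN)
  expect_equal(got$TN, want$TN)
  expect_equal(got$TP + got$FP + got$FN + got$TN, 256 - sum(e))

  idc <- confusion(p, p)
  expect_equal(idc$FP + idc$FN, 0L)

  empty_pred <- confusion(matrix(FALSE, 16, 16), t)
  expect_equal(empty_pred$FN, sum(t))
  expect_equal(empty_pred$TP, 0L)
  expect_error(confusion(p, matrix(TRUE, 8, 8)), "shape")
})

test_that("dice follows its formula, conventions and monotonicity", {
  cc <- structure(list(TP = 50L, FP = 25L, FN = 25L, TN = 0L),
                  class = "confusion_counts")
  expect_equal(dice(cc), 2 / 3)
  both_empty <- structure(list(TP = 0L, FP = 0L, FN = 0L, TN = 100L),
                          class = "confusion_counts")
  expect_equal(dice(both_empty), 1)

  a <- matrix(FALSE, 16, 16); a[1:4, 1:4] <- TRUE
  b <- matrix(FALSE, 16, 16); b[9:12, 9:12] <- TRUE
  expect_equal(dice(confusion(a, a)), 1)
  expect_equal(dice(confusion(a, b)), 0)
  # symmetry and non-increase when adding disjoint false positives
  set.seed(12)
  t <- matrix(runif(256) > 0.6, 16, 16)
  p <- t; p[1:2, ] <- FALSE
  expect_equal(dice(confusion(p, t)), dice(confusion(t, p)))
  p <- t
  d_prev <- dice(confusion(p, t))
  bg <- which(!t)
  for (j in seq(10, 50, by = 10)) {
    p[bg[seq_len(j)]] <- TRUE        # grow the disjoint FP set
    d_now <- dice(confusion(p, t))
    expect_lte(d_now, d_prev + 1e-12)
    d_prev <- d_now
  }
})

test_that("NPI arithmetic, bounds and monotonicity", {
  expect_equal(npi(100, 1000, 200), 0.125)
  expect_equal(npi(0, 1000, 200), 0)
  expect_equal(npi(800, 1000, 200), 1)
  expect_error(npi(10, 100, 100), "positive")
  expect_error(npi(900, 1000, 200), "within")
  # increasing in area_np and in area_elim
  expect_gt(npi(200, 1000, 100), npi(100, 1000, 100))
  expect_gt(npi(100, 1000, 300), npi(100, 1000, 100))
})

test_that("Spearman correlation matches a rank-based oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9)
  expect_equal(spearman_cor(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  set.seed(13)
  for (i in 1:5) {
    a <- sample(20, 8, replace = TRUE)   # replacement forces ties
    b <- sample(20, 8, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_cor(a, b)$rho, bf_spearman_rho(a, b),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  a <- c(0.2, 0.9, 0.4, 0.6, 0.1, 0.8)
  b <- c(1, 5, 2, 6, 3, 4)
  expect_equal(spearman_cor(exp(a), b)$rho, spearman_cor(a, b)$rho)
  expect_error(spearman_cor(1:5, 1:4), "length")
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman limits and outlier flagging", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(bland_altman(a, a)$mean_diff, 0)
  expect_length(bland_altman(a, a)$outlier_ids, 0)

  # symmetric +/- c differences: mean 0, limits +/- 1.96 sd
  b <- c(0.1, 0.3, 0.2, 0.5)
  d <- c(0.05, -0.05, 0.05, -0.05)
  ba <- bland_altman(b + d, b)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high, 1.96 * sd(d))
  expect_equal(ba$means, b + d / 2)

  # one extreme difference among near-zero ones is flagged
  g <- seq(0.1, 1, length.out = 10)
  h <- g; h[7] <- g[7] + 0.5
  ba2 <- bland_altman(h, g, ids = letters[1:10])
  expect_identical(ba2$outlier_ids, "g")
  expect_error(bland_altman(1:4, 1:3), "length")
})

test_that("batch evaluation aggregates per-image records consistently", {
  suite <- generate_suite(3, tiny_phantom_config(), base_seed = 60)
  preds <- lapply(suite, function(s) vmseg_segment(s$image, s$elim))
  recs <- evaluate_batch(preds,
                         lapply(suite, `[[`, "truth"),
                         lapply(suite, `[[`, "elim"),
                         ids = paste0("s", 1:3))
  expect_equal(nrow(recs), 3)
  expect_true(all(recs$dice >= 0 & recs$dice <= 1))
  # spot-check one record against direct metric calls
  cc <- confusion(preds[[2]], suite[[2]]$truth, suite[[2]]$elim)
  expect_equal(recs$dice[2], dice(cc))
  expect_equal(recs$npi_ground_truth[2],
               npi_from_mask(suite[[2]]$truth, suite[[2]]$elim))
  summ <- summarize_evaluation(recs)
  expect_equal(summ$mean_dice, mean(recs$dice))
  expect_equal(summ$npi_spearman$rho,
               spearman_cor(recs$npi_estimated, recs$npi_ground_truth)$rho)
})
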