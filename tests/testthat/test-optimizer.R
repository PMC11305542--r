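test_that("dev/test split is reproducible, exhaustive and group-aware", {
  ids <- paste0("img", 1:10)
  sp <- split_dev_test(ids, 0.7, seed = 5)
  expect_length(sp$dev, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$dev, sp$test), ids)
  expect_identical(sp, split_dev_test(ids, 0.7, seed = 5))

  # both eyes of a patient stay on the same side
  eyes <- paste0("p", rep(1:6, each = 2), c("_OD", "_OS"))
  pat <- rep(1:6, each = 2)
  spg <- split_dev_test(eyes, 0.7, seed = 9, groups = pat)
  pat_of <- function(v) sub("_O[DS]$", "", v)
  expect_length(intersect(pat_of(spg$dev), pat_of(spg$test)), 0)

  expect_error(split_dev_test("one", 0.7), "at least 2")
})

test_that("a single-point grid reproduces direct evaluation", {
  ds <- tiny_dataset(1, base_seed = 70)
  g <- grid_spec(intensity_range = 75, variance_range = 17, morph_range = 1,
                 kernel_combos = list(c(3, 5)))
  res <- grid_search(ds, g)
  direct <- vmseg_segment(ds[[1]]$image, ds[[1]]$elim, vmseg_params())
  expect_equal(res$best_mean_dice,
               dice(confusion(direct, ds[[1]]$truth, ds[[1]]$elim)))
  expect_equal(res$best_params$variance_threshold, 17)
  expect_equal(nrow(res$table), 1)
})

test_that("grid search maximizes mean Dice and reports consistent marginals", {
  ds <- tiny_dataset(2, base_seed = 75)
  g <- grid_spec(intensity_range = c(70, 80), variance_range = c(13, 17, 21),
                 morph_range = 0:1, kernel_combos = list(3, c(3, 5)))
  res <- grid_search(ds, g)
  expect_true(all(res$best_mean_dice >= res$table$mean_dice))
  # recompute the best point from scratch through the public pipeline
  bp <- res$best_params
  redo <- mean(vapply(ds, function(s)
    dice(confusion(vmseg_segment(s$image, s$elim, bp), s$truth, s$elim)),
    numeric(1)))
  expect_equal(redo, res$best_mean_dice)
  # marginal curves pass through the optimum
  expect_true(any(abs(res$marginals$variance$mean_dice - res$best_mean_dice) < 1e-12))
  expect_equal(nrow(res$marginals$variance), 3)
  expect_error(grid_search(list(), g), "empty")
})

test_that("ties break toward the smallest thresholds", {
  # constant dark image with an all-true truth: every grid point scores 1
  ds <- list(list(image = matrix(20, 64, 64), truth = matrix(TRUE, 64, 64)))
  g <- grid_spec(intensity_range = c(60, 75), variance_range = c(12, 17),
                 morph_range = 0:1, kernel_combos = list(3, 5))
  res <- grid_search(ds, g)
  expect_equal(res$best_mean_dice, 1)
  expect_equal(res$best_params$variance_threshold, 12)
  expect_equal(res$best_params$intensity_threshold, 60)
  expect_equal(res$best_params$morph_iterations, 0L)
  expect_equal(res$best_params$kernel_sizes, 3L)
})

test_that("robustness over identical subsets has zero dispersion", {
  ds <- tiny_dataset(2, base_seed = 80)
  g <- grid_spec(intensity_range = c(70, 80), variance_range = c(15, 19),
                 morph_range = 1, kernel_combos = list(c(3, 5)))
  rob <- robustness_analysis(ds, g, n_repeats = 2, subset_fraction = 1,
                             seed = 3)
  expect_equal(rob$summary$sd, c(0, 0, 0))
  expect_identical(rob$optima$variance[1], rob$optima$variance[2])
  expect_error(robustness_analysis(ds, g, n_repeats = 2,
                                   subset_fraction = 0.2, seed = 1),
               "subset")
})
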