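test_that("normalization maps linearly to [0, 255] and degenerates to zero", {
  m <- matrix(10, 64, 64)
  m[1, 1] <- 110; m[2, 2] <- 60
  nm <- normalize_image(m)
  expect_equal(nm[2, 2], 127.5)
  expect_equal(nm[1, 1], 255)
  expect_true(all(normalize_image(matrix(42, 64, 64)) == 0))
  # already full-range image: equals the direct formula
  set.seed(1)
  r <- matrix(runif(32 * 32, 0, 255), 32, 32)
  r[1] <- 0; r[2] <- 255
  expect_equal(normalize_image(r), (r - min(r)) * 255 / (max(r) - min(r)))
})

test_that("bilateral filter preserves constants, edges, and reduces noise", {
  expect_equal(bilateral_smooth(matrix(80, 32, 32)), matrix(80, 32, 32))

  # step edge: per-row gradient argmax unchanged
  step <- cbind(matrix(40, 32, 16), matrix(200, 32, 16))
  sm <- bilateral_smooth(step)
  argmax_grad <- function(m) apply(m, 1, function(r) which.max(abs(diff(r))))
  expect_equal(argmax_grad(sm), argmax_grad(step))
  eps <- 1e-9   # convex combination: bounded by the input range up to fp error
  expect_true(min(sm) >= min(step) - eps && max(sm) <= max(step) + eps)

  # salt noise on a flat background is damped
  set.seed(3)
  salt <- matrix(100, 32, 32)
  salt[sample(length(salt), 60)] <- 130
  expect_lt(var(as.numeric(bilateral_smooth(salt))), var(as.numeric(salt)))
})

test_that("local variance map matches closed forms", {
  expect_true(all(local_variance_map(matrix(9, 32, 32), 3)$values == 0))

  # 0/255 checkerboard: interior windows hold k in {4, 5} bright pixels
  cb <- outer(1:32, 1:32, function(i, j) ((i + j) %% 2) * 255)
  vm <- local_variance_map(cb, 3)$values
  expected <- 255^2 * c(4 * 5, 5 * 4) / 81
  expect_true(all(abs(vm[2:31, 2:31] - expected[1]) < 1e-6))

  expect_error(local_variance_map(matrix(0, 32, 32), 4), "3, 5, 7")
  expect_error(local_variance_map(matrix(0, 32, 32), 9), "3, 5, 7")
})

test_that("combining variance maps is the pixelwise mean", {
  a <- variance_map(matrix(4, 16, 16), "raw")
  b <- variance_map(matrix(10, 16, 16), "raw")
  expect_equal(combine_variance_maps(list(a))$values, a$values)
  expect_true(all(combine_variance_maps(list(a, b))$values == 7))
  set.seed(4)
  ms <- lapply(1:3, function(i) variance_map(matrix(runif(64), 8, 8), "raw"))
  expect_equal(combine_variance_maps(ms)$values,
               (ms[[1]]$values + ms[[2]]$values + ms[[3]]$values) / 3)
  bad <- variance_map(matrix(1, 4, 4), "raw")
  expect_error(combine_variance_maps(list(a, bad)), "shape")
})

test_that("modified map orients homogeneous areas low and overrides vessels", {
  # constant dark image: zero variance everywhere, no override fires
  img <- matrix(10, 32, 32)
  vm <- local_variance_map(img, 3)
  expect_true(all(modify_variance_map(vm, img, 75)$values == 0))

  # a bright pixel is forced to 255 whatever its variance
  img2 <- matrix(10, 32, 32); img2[5, 5] <- 255
  vm2 <- local_variance_map(img2, 3)
  mod2 <- modify_variance_map(vm2, img2, 75)
  expect_equal(mod2$values[5, 5], 255)

  # noisy patch carries higher modified values than a flat dark patch
  set.seed(5)
  img3 <- matrix(30, 64, 64)
  img3[1:32, ] <- img3[1:32, ] + round(rnorm(32 * 64, 0, 15))
  img3 <- pmin(pmax(img3, 0), 74)   # keep below the override threshold
  mod3 <- modify_variance_map(local_variance_map(img3, 3), img3, 75)
  expect_gt(mean(mod3$values[1:32, ]), mean(mod3$values[40:64, ]))
})

test_that("binarization is strictly below the variance threshold", {
  v <- matrix(10, 16, 16); v[1, ] <- 17; v[2, ] <- 20
  mask <- binarize(variance_map(v, "modified"), 17)
  expect_true(all(mask$nonperfusion[3:16, ]))
  expect_false(any(mask$nonperfusion[1:2, ]))
  expect_true(all(binarize(variance_map(matrix(0, 16, 16), "modified"), 17)$nonperfusion))
  expect_false(any(binarize(variance_map(matrix(255, 16, 16), "modified"), 17)$nonperfusion))
})

test_that("hole filling and size filtering behave at the boundary", {
  # 300-px blob with a 20-px hole is retained, hole filled
  m <- matrix(FALSE, 64, 64)
  m[10:29, 10:25] <- TRUE            # 20 x 16 = 320 px
  m[15:19, 15:18] <- FALSE           # 20-px interior hole
  out <- fill_and_filter(m, 250)
  expect_true(all(out$nonperfusion[10:29, 10:25]))
  expect_equal(sum(out$nonperfusion), 320)
})

test_that("full segmentation handles degenerate images", {
  # uniform dark frame: one full-frame non-perfusion region
  full <- vmseg_segment(matrix(30, 64, 64))
  expect_true(all(full$nonperfusion))

  # dense bright noise: every structure is high-variance or vessel-bright
  set.seed(6)
  noise <- matrix(runif(96 * 96, 0, 255), 96, 96)
  expect_equal(sum(vmseg_segment(noise)$nonperfusion), 0)
})

test_that("segmentation respects the elimination mask and input shapes", {
  s <- generate_phantom(tiny_phantom_config(seed = 21))
  mask <- vmseg_segment(s$image, s$elim)
  expect_false(any(mask$nonperfusion & s$elim$excluded))
  bad_elim <- matrix(FALSE, 32, 32)
  expect_error(vmseg_segment(s$image, bad_elim), "shape")
})
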