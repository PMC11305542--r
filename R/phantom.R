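#' Phantom generator configuration
#'
#' Synthetic widefield OCT-A-like images with known non-perfusion ground
#' truth. The phantom emulates the features the segmentation keys on: a
#' bright curvilinear vessel network over speckle, smooth dark low-variance
#' dropout patches, a center-bright/periphery-dim radial gradient (the
#' montage vignetting that defeats global binarization), and white eliminated
#' regions. Defaults give a high dropout contrast: background mean 140 with
#' speckle sigma 20 versus patch mean 40 with quarter-amplitude noise.
#'
#' @param size Image side in pixels (>= 64; default 512).
#' @param n_patches Number of non-perfusion patches (default 4).
#' @param patch_radius_range Semi-axis range of the patches in px (>= 8).
#' @param vessel_density Target fraction of vessel pixels (default 0.18).
#' @param speckle_sigma Background speckle sd in intensity units (default 20).
#' @param gradient_strength Center-to-periphery brightness falloff ratio in
#'   `[0, 1]` (default 0.2: the far periphery is 20% dimmer than the center).
#' @param elim_fraction Fraction of the frame painted white as eliminated,
#'   in `[0, 0.5)` (default 0.04).
#' @param seed Integer seed; all phantom randomness flows from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size = 512, n_patches = 4,
                           patch_radius_range = c(25, 45),
                           vessel_density = 0.18, speckle_sigma = 20,
                           gradient_strength = 0.2, elim_fraction = 0.04,
                           seed = 1L) {
  stopifnot(size >= 64, n_patches >= 0,
            length(patch_radius_range) == 2L, patch_radius_range[1L] >= 8,
            patch_radius_range[2L] >= patch_radius_range[1L],
            vessel_density >= 0, vessel_density < 1,
            speckle_sigma >= 0, gradient_strength >= 0, gradient_strength <= 1,
            elim_fraction >= 0, elim_fraction < 0.5)
  structure(list(size = as.integer(size), n_patches = as.integer(n_patches),
                 patch_radius_range = patch_radius_range,
                 vessel_density = vessel_density,
                 speckle_sigma = speckle_sigma,
                 gradient_strength = gradient_strength,
                 elim_fraction = elim_fraction, seed = as.integer(seed)),
            class = "phantom_config")
}

# one biased random walk; returns integer pixel coordinates (may repeat)
walk_path <- function(start, n_steps, turn_sd = 0.22) {
  ang <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(n_steps, 0, turn_sd)))
  x <- start[1L] + cumsum(cos(ang))
  y <- start[2L] + cumsum(sin(ang))
  cbind(round(x), round(y))
}

#' Generate one synthetic phantom sample
#'
#' Background speckle modulated by a radial brightness gradient; bright
#' vessels drawn as biased random walks (about half of them branching off
#' existing vessels) with stroke widths of 1-4 px until the target vessel
#' density is reached; dark smooth dropout patches as radially jittered
#' ellipses where vessels are erased and noise amplitude is reduced to a
#' quarter; an eliminated border band painted white. Deterministic for a
#' fixed seed.
#'
#' @param config A [phantom_config].
#' @return An object of class `phantom_sample`: `image` ([retinal_image]),
#'   `truth` ([segmentation_mask]), `elim` ([elimination_mask]), `config`,
#'   and `analytic_patch_area` (the summed closed-form patch areas, for
#'   bookkeeping checks).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  n <- cfg$size
  rowm <- matrix(rep(seq_len(n), n), n, n)
  colm <- matrix(rep(seq_len(n), each = n), n, n)
  ctr <- (n + 1) / 2
  rmax <- sqrt(2) * (n - 1) / 2
  grad <- 1 - cfg$gradient_strength * ((rowm - ctr)^2 + (colm - ctr)^2) / rmax^2

  base_mean <- 140
  vessel_mean <- 235
  patch_mean <- 40

  img <- (base_mean + matrix(stats::rnorm(n * n, 0, cfg$speckle_sigma), n, n)) *
    grad

  # elimination: a band along one randomly chosen border, painted white later
  elim <- matrix(FALSE, n, n)
  if (cfg$elim_fraction > 0) {
    side <- sample(4L, 1L)
    depth <- max(1L, round(cfg$elim_fraction * n))
    if (side == 1L) elim[seq_len(depth), ] <- TRUE
    if (side == 2L) elim[(n - depth + 1L):n, ] <- TRUE
    if (side == 3L) elim[, seq_len(depth)] <- TRUE
    if (side == 4L) elim[, (n - depth + 1L):n] <- TRUE
  }

  # vessels: random walks, some branching from existing vessel pixels
  vessel <- matrix(FALSE, n, n)
  target <- cfg$vessel_density * n * n
  guard <- 0L
  while (sum(vessel) < target && guard < 5000L) {
    guard <- guard + 1L
    start <- if (any(vessel) && stats::runif(1) < 0.5) {
      idx <- which(vessel)
      i <- idx[sample.int(length(idx), 1L)]
      c((i - 1L) %% n + 1L, (i - 1L) %/% n + 1L)
    } else {
      c(stats::runif(1, 1, n), stats::runif(1, 1, n))
    }
    pts <- walk_path(start, n_steps = n)
    keep <- pts[, 1L] >= 1 & pts[, 1L] <= n & pts[, 2L] >= 1 & pts[, 2L] <= n
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) == 0L) next
    stroke <- matrix(0, n, n)
    stroke[pts] <- 1
    w <- sample(1:4, 1L, prob = c(0.35, 0.3, 0.25, 0.1))
    if (w >= 2L) stroke <- EBImage::dilate(stroke, matrix(1L, 2L, 2L))
    if (w >= 3L) stroke <- EBImage::dilate(stroke, cross_kernel(3L))
    if (w >= 4L) stroke <- EBImage::dilate(stroke, matrix(1L, 2L, 2L))
    vessel <- vessel | (stroke > 0)
  }
  nv <- sum(vessel)
  img[vessel] <- (vessel_mean + stats::rnorm(nv, 0, 12)) * grad[vessel]

  # non-perfusion patches: radially jittered ellipses, dark and smooth
  truth <- matrix(FALSE, n, n)
  analytic_area <- 0
  jitter_amp <- 0.12
  for (p in seq_len(cfg$n_patches)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      a <- stats::runif(1, cfg$patch_radius_range[1L], cfg$patch_radius_range[2L])
      b <- stats::runif(1, cfg$patch_radius_range[1L], cfg$patch_radius_range[2L])
      rmaxp <- max(a, b) * (1 + jitter_amp)
      margin <- rmaxp + 6
      if (2 * margin >= n)
        stop("phantom generation failed: patch radius too large for image size",
             call. = FALSE)
      cx <- stats::runif(1, margin, n - margin)
      cy <- stats::runif(1, margin, n - margin)
      phi <- stats::runif(1, 0, pi)
      k_j <- sample(2:5, 1L)
      ph_j <- stats::runif(1, 0, 2 * pi)
      # bounding box in array coords
      r0 <- max(1L, floor(cx - rmaxp)); r1 <- min(n, ceiling(cx + rmaxp))
      c0 <- max(1L, floor(cy - rmaxp)); c1 <- min(n, ceiling(cy + rmaxp))
      rs <- rowm[r0:r1, c0:c1] - cx
      cs <- colm[r0:r1, c0:c1] - cy
      xr <- rs * cos(phi) + cs * sin(phi)
      yr <- -rs * sin(phi) + cs * cos(phi)
      rho <- sqrt((xr / a)^2 + (yr / b)^2)
      th <- atan2(yr / b, xr / a)
      inside <- rho <= 1 + jitter_amp * sin(k_j * th + ph_j)
      # reject patches touching the eliminated band or an existing patch
      if (any(inside & elim[r0:r1, c0:c1])) next
      if (any(inside & truth[r0:r1, c0:c1])) next
      block <- matrix(FALSE, n, n)
      block[r0:r1, c0:c1] <- inside
      truth <- truth | block
      npx <- sum(inside)
      img[block] <- (patch_mean +
        stats::rnorm(npx, 0, cfg$speckle_sigma / 4)) * grad[block]
      analytic_area <- analytic_area + pi * a * b * (1 + jitter_amp^2 / 2)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("phantom generation failed: could not place patch ", p,
           " away from eliminated/occupied regions", call. = FALSE)
  }

  img[elim] <- 255
  img <- pmin(pmax(img, 0), 255)
  structure(list(image = retinal_image(img),
                 truth = segmentation_mask(truth),
                 elim = elimination_mask(elim),
                 config = cfg,
                 analytic_patch_area = analytic_area),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d, %d truth px, %d eliminated px (seed %d)\n",
              x$image$height, x$image$width, sum(x$truth$nonperfusion),
              sum(x$elim$excluded), x$config$seed))
  invisible(x)
}

#' Generate a suite of phantom samples
#'
#' Sample `i` uses seed `base_seed + i - 1` and a patch count cycling through
#' `1..config$n_patches`, so ground-truth NPIs spread over a range.
#'
#' @param n Number of samples (>= 1).
#' @param config A [phantom_config]; its `seed` is overridden per sample.
#' @param base_seed First seed.
#' @return List of `phantom_sample` objects.
#' @export
generate_suite <- function(n, config = phantom_config(), base_seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1L)
    if (config$n_patches > 0L)
      cfg$n_patches <- 1L + (i - 1L) %% config$n_patches
    generate_phantom(cfg)
  })
}
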