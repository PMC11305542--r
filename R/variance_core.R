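#' Segmentation pipeline parameters
#'
#' Tunable parameters of the variance-map segmentation pipeline. The defaults
#' are the optimum found by grid search on a widefield OCT-A development set:
#' variance maps from 3x3 and 5x5 windows averaged, a variance threshold of 17
#' on the 0-255 modified-map scale, a vessel-override intensity threshold of
#' 75 on the normalized image, and one morphology iteration.
#'
#' @param kernel_sizes Odd window widths for the local variance maps; nonempty
#'   subset of `c(3, 5, 7)`.
#' @param variance_threshold Binarization threshold on the modified variance
#'   map (0-255 scale); pixels strictly below it are non-perfusion candidates.
#' @param intensity_threshold Normalized-intensity threshold at or above which
#'   a pixel is treated as vessel and forced to 255 in the modified map.
#' @param morph_iterations Number of grayscale closing-then-opening iterations
#'   (0 skips morphology).
#' @param size_threshold_px Minimum filled component area kept, in pixels.
#' @param bilateral_diameter Bilateral filter window diameter in pixels.
#' @param bilateral_sigma Bilateral filter sigma, used for both the spatial
#'   and the intensity weight.
#' @param morph_kernel_size Side of the cross-shaped structuring element.
#' @return An object of class `vmseg_params`.
#' @export
vmseg_params <- function(kernel_sizes = c(3, 5),
                         variance_threshold = 17,
                         intensity_threshold = 75,
                         morph_iterations = 1,
                         size_threshold_px = 250,
                         bilateral_diameter = 9,
                         bilateral_sigma = 40,
                         morph_kernel_size = 5) {
  kernel_sizes <- sort(unique(as.integer(kernel_sizes)))
  if (length(kernel_sizes) == 0L || !all(kernel_sizes %in% c(3L, 5L, 7L)))
    stop("kernel_sizes must be a nonempty subset of {3, 5, 7}", call. = FALSE)
  stopifnot(intensity_threshold >= 0, intensity_threshold <= 255,
            variance_threshold > 0,
            morph_iterations >= 0, morph_iterations == as.integer(morph_iterations),
            size_threshold_px >= 1,
            bilateral_diameter >= 3, bilateral_diameter %% 2 == 1,
            bilateral_sigma > 0,
            morph_kernel_size >= 3, morph_kernel_size %% 2 == 1)
  structure(list(kernel_sizes = kernel_sizes,
                 variance_threshold = variance_threshold,
                 intensity_threshold = intensity_threshold,
                 morph_iterations = as.integer(morph_iterations),
                 size_threshold_px = as.integer(size_threshold_px),
                 bilateral_diameter = as.integer(bilateral_diameter),
                 bilateral_sigma = bilateral_sigma,
                 morph_kernel_size = as.integer(morph_kernel_size)),
            class = "vmseg_params")
}

#' @export
print.vmseg_params <- function(x, ...) {
  cat(sprintf(paste0("<vmseg_params> kernels {%s}, variance_threshold %.1f, ",
                     "intensity_threshold %.0f, morph_iterations %d, ",
                     "size_threshold %d px\n"),
              paste(x$kernel_sizes, collapse = ","), x$variance_threshold,
              x$intensity_threshold, x$morph_iterations, x$size_threshold_px))
  invisible(x)
}

#' Local spatial variance map
#'
#' @param values Non-negative numeric matrix (raw stage) or values in
#'   `[0, 255]` (modified stage).
#' @param stage `"raw"` (unbounded variances) or `"modified"` (rescaled,
#'   vessel-overridden 0-255 map).
#' @return An object of class `variance_map`.
#' @export
variance_map <- function(values, stage = c("raw", "modified")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), is.numeric(values))
  if (min(values) < -1e-9)
    stop("variance values must be non-negative", call. = FALSE)
  if (stage == "modified" && max(values) > 255 + 1e-9)
    stop("modified variance map must lie in [0, 255]", call. = FALSE)
  structure(list(values = values, stage = stage), class = "variance_map")
}

#' @export
print.variance_map <- function(x, ...) {
  cat(sprintf("<variance_map stage=%s> %d x %d, range [%.2f, %.2f]\n",
              x$stage, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# reflect padding (edge pixel included in the mirror) by radius r
reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(r < nr, r < nc)
  m[c(r:1, 1:nr, nr:(nr - r + 1L)), c(r:1, 1:nc, nc:(nc - r + 1L))]
}

#' Min-max normalize an image to the full 8-bit range
#'
#' Linear rescale of intensities to `[0, 255]`; a constant image maps to all
#' zeros.
#'
#' @param image A [retinal_image] or numeric matrix.
#' @return Same type as the input, intensities spanning `[0, 255]`.
#' @export
normalize_image <- function(image) {
  px <- as_pixel_matrix(image)
  mn <- min(px); mx <- max(px)
  out <- if (mx > mn) (px - mn) * (255 / (mx - mn)) else px * 0
  rewrap_image(image, out)
}

rewrap_image <- function(template, px) {
  if (inherits(template, "retinal_image"))
    retinal_image(px, pixel_pitch_mm = template$pixel_pitch_mm)
  else px
}

#' Edge-preserving bilateral smoothing
#'
#' Classic bilateral filter: each output pixel is a weighted mean of its
#' `diameter` x `diameter` neighborhood, weights being the product of a
#' spatial Gaussian and an intensity-difference Gaussian (both with the same
#' `sigma`, matching the pipeline convention). Borders use reflect padding.
#' Because the output is a convex combination of input values it never leaves
#' the input range, and a constant image is returned unchanged.
#'
#' @param image A [retinal_image] or numeric matrix.
#' @param diameter Odd window diameter in pixels (default 9).
#' @param sigma Gaussian sigma shared by the spatial and intensity weights
#'   (default 40).
#' @return Same type as the input.
#' @export
bilateral_smooth <- function(image, diameter = 9, sigma = 40) {
  stopifnot(diameter >= 3, diameter %% 2 == 1, sigma > 0)
  px <- as_pixel_matrix(image)
  r <- diameter %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  p <- reflect_pad(px, r)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  inv2s2 <- 1 / (2 * sigma^2)
  for (dx in -r:r) {
    for (dy in -r:r) {
      ws <- exp(-(dx * dx + dy * dy) * inv2s2)
      sh <- p[(r + 1L + dx):(r + nr + dx), (r + 1L + dy):(r + nc + dy)]
      w <- ws * exp(-(sh - px)^2 * inv2s2)
      num <- num + w * sh
      den <- den + w
    }
  }
  rewrap_image(image, num / den)
}

#' Local variance map of an image
#'
#' Each pixel is replaced by the population variance of its
#' `window` x `window` neighborhood, computed as `E[X^2] - E[X]^2` with
#' reflect padding at the borders; tiny negative values from floating-point
#' cancellation are clipped to zero.
#'
#' @param image A [retinal_image] or numeric matrix.
#' @param window Odd window width, one of 3, 5, 7.
#' @return A [variance_map] at stage `"raw"`.
#' @export
local_variance_map <- function(image, window) {
  if (length(window) != 1L || !(window %in% c(3, 5, 7)))
    stop("window must be one of 3, 5, 7", call. = FALSE)
  px <- as_pixel_matrix(image)
  r <- as.integer(window) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  p <- reflect_pad(px, r)
  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
  for (dx in -r:r) {
    for (dy in -r:r) {
      sh <- p[(r + 1L + dx):(r + nr + dx), (r + 1L + dy):(r + nc + dy)]
      s <- s + sh
      s2 <- s2 + sh * sh
    }
  }
  n <- (2 * r + 1)^2
  v <- s2 / n - (s / n)^2
  variance_map(pmax(v, 0), stage = "raw")
}

#' Average several raw variance maps pixelwise
#'
#' @param maps List of [variance_map] objects at stage `"raw"`, same shape.
#' @return A [variance_map] at stage `"raw"`.
#' @export
combine_variance_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  vals <- lapply(maps, function(m) {
    stopifnot(inherits(m, "variance_map"))
    if (m$stage != "raw") stop("can only combine raw variance maps", call. = FALSE)
    m$values
  })
  d <- dim(vals[[1L]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1L))))
    stop("variance maps must share the same shape", call. = FALSE)
  variance_map(Reduce(`+`, vals) / length(vals), stage = "raw")
}

#' Rescale a raw variance map and apply the vessel override
#'
#' The raw variance map is min-max rescaled to `[0, 255]`, oriented so that
#' homogeneous (low-variance) areas carry low values and textured areas high
#' values. Then every pixel whose intensity in `original` (the normalized
#' source image) is at or above `intensity_threshold` is forced to 255, so
#' that bright vessel pixels can never be selected as non-perfusion however
#' low their local variance.
#'
#' @param vmap A [variance_map] at stage `"raw"`.
#' @param original The min-max normalized source image ([retinal_image] or
#'   matrix), same shape as `vmap`.
#' @param intensity_threshold Override threshold in `[0, 255]`.
#' @return A [variance_map] at stage `"modified"`.
#' @export
modify_variance_map <- function(vmap, original, intensity_threshold) {
  stopifnot(inherits(vmap, "variance_map"), vmap$stage == "raw",
            intensity_threshold >= 0, intensity_threshold <= 255)
  px <- as_pixel_matrix(original)
  if (!identical(dim(px), dim(vmap$values)))
    stop("image and variance map shapes differ", call. = FALSE)
  v <- vmap$values
  mn <- min(v); mx <- max(v)
  out <- if (mx > mn) (v - mn) * (255 / (mx - mn)) else v * 0
  out[px >= intensity_threshold] <- 255
  variance_map(out, stage = "modified")
}

cross_kernel <- function(size = 5L) {
  k <- matrix(0L, size, size)
  mid <- (size + 1L) %/% 2L
  k[mid, ] <- 1L
  k[, mid] <- 1L
  k
}

#' Grayscale morphological cleanup of the modified variance map
#'
#' Applies grayscale closing `iterations` times, then grayscale opening
#' `iterations` times, with a cross-shaped structuring element. Closing fills
#' small dark pits (isolated candidate specks inside vessel-rich texture);
#' opening removes small bright peaks. `iterations = 0` returns the input
#' unchanged.
#'
#' @param vmap A [variance_map] at stage `"modified"`.
#' @param iterations Non-negative integer.
#' @param kernel_size Side of the cross structuring element (default 5).
#' @return A [variance_map] at stage `"modified"`.
#' @export
morphology_clean <- function(vmap, iterations = 1, kernel_size = 5) {
  stopifnot(inherits(vmap, "variance_map"), vmap$stage == "modified",
            iterations >= 0, iterations == as.integer(iterations))
  if (iterations == 0) return(vmap)
  k <- cross_kernel(as.integer(kernel_size))
  v <- vmap$values / 255   # EBImage grayscale morphology works on [0,1]
  for (i in seq_len(iterations)) v <- EBImage::closing(v, k)
  for (i in seq_len(iterations)) v <- EBImage::opening(v, k)
  variance_map(matrix(pmin(pmax(as.numeric(v), 0), 1), nrow(vmap$values),
                      ncol(vmap$values)) * 255, stage = "modified")
}

#' Binarize the modified variance map
#'
#' Pixels strictly below `variance_threshold` — dark and locally homogeneous —
#' become non-perfusion candidates.
#'
#' @param vmap A [variance_map] at stage `"modified"`.
#' @param variance_threshold Threshold in `(0, 255)`.
#' @return A [segmentation_mask].
#' @export
binarize <- function(vmap, variance_threshold) {
  stopifnot(inherits(vmap, "variance_map"), vmap$stage == "modified",
            variance_threshold > 0, variance_threshold < 255)
  segmentation_mask(vmap$values < variance_threshold)
}

#' Fill component holes and drop small components
#'
#' Interior holes (background regions not 4-connected to the frame border)
#' are filled, then foreground components (8-connectivity) with filled area
#' below `size_threshold_px` are removed. Idempotent.
#'
#' @param mask A [segmentation_mask] or logical matrix.
#' @param size_threshold_px Minimum kept component area in pixels
#'   (a component of exactly this area is kept).
#' @return A [segmentation_mask].
#' @export
fill_and_filter <- function(mask, size_threshold_px = 250) {
  stopifnot(size_threshold_px >= 1)
  m <- as_logical_matrix(mask)
  filled <- fill_holes(m)
  lab <- label_components(filled, connectivity = 8L)
  if (max(lab) == 0L) return(segmentation_mask(filled))
  areas <- component_areas(lab)
  keep <- which(areas >= size_threshold_px)
  segmentation_mask(matrix(lab %in% keep, nrow(m), ncol(m)))
}

#' Segment retinal non-perfusion on an en-face OCT-A image
#'
#' Full pipeline: min-max normalization, bilateral pre-filtering, local
#' variance maps for each configured window size averaged into one map,
#' rescaling plus bright-pixel (vessel) override, a second bilateral pass,
#' grayscale morphology, binarization below the variance threshold, hole
#' filling and component size filtering. Eliminated pixels are forced to 255
#' in the modified map (never candidates) and removed from the final mask.
#' Fully deterministic: identical inputs give bit-identical masks.
#'
#' @param image A [retinal_image] or numeric matrix in `[0, 255]`.
#' @param elim Optional [elimination_mask] (or logical matrix) of excluded
#'   pixels; `NULL` means nothing is excluded.
#' @param params A [vmseg_params] object.
#' @return A [segmentation_mask] of non-perfusion, never intersecting `elim`.
#' @export
vmseg_segment <- function(image, elim = NULL, params = vmseg_params()) {
  stopifnot(inherits(params, "vmseg_params"))
  px <- as_pixel_matrix(image)
  ex <- if (is.null(elim)) NULL else as_logical_matrix(elim)
  if (!is.null(ex) && !identical(dim(ex), dim(px)))
    stop("elimination mask shape differs from image", call. = FALSE)

  norm <- normalize_image(px)
  sm <- bilateral_smooth(norm, params$bilateral_diameter, params$bilateral_sigma)
  vmaps <- lapply(params$kernel_sizes, function(k) local_variance_map(sm, k))
  vmap <- combine_variance_maps(vmaps)
  mod <- modify_variance_map(vmap, norm, params$intensity_threshold)
  if (!is.null(ex)) mod$values[ex] <- 255
  mod <- variance_map(
    as_pixel_matrix(bilateral_smooth(mod$values, params$bilateral_diameter,
                                     params$bilateral_sigma)),
    stage = "modified")
  mod <- morphology_clean(mod, params$morph_iterations, params$morph_kernel_size)
  bin <- binarize(mod, params$variance_threshold)
  out <- fill_and_filter(bin, params$size_threshold_px)
  if (!is.null(ex)) out$nonperfusion[ex] <- FALSE
  out
}
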