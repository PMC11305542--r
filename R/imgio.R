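#' Retinal en-face OCT-A image
#'
#' Container for a 2D grayscale en-face full-retina slab. Intensities are kept
#' on the 8-bit scale `[0, 255]` regardless of the source bit depth; the
#' optional pixel pitch records the physical size of one pixel side so that
#' areas can be converted to mm^2 downstream.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]` (rows = image
#'   rows, origin at the top-left, 0-based pixel coordinates in any reporting).
#' @param pixel_pitch_mm Optional positive scalar, physical pixel side in mm.
#' @return An object of class `retinal_image` with fields `pixels`, `height`,
#'   `width` and `pixel_pitch_mm`.
#' @export
retinal_image <- function(pixels, pixel_pitch_mm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 32L || ncol(pixels) < 32L)
    stop("image must be at least 32x32 pixels", call. = FALSE)
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must be finite and within [0, 255]", call. = FALSE)
  if (!is.null(pixel_pitch_mm)) {
    stopifnot(is.numeric(pixel_pitch_mm), length(pixel_pitch_mm) == 1L,
              pixel_pitch_mm > 0)
  }
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "retinal_image")
}

#' @export
print.retinal_image <- function(x, ...) {
  cat(sprintf("<retinal_image> %d x %d px, intensity range [%.1f, %.1f]%s\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              if (is.null(x$pixel_pitch_mm)) ""
              else sprintf(", pitch %.4f mm/px", x$pixel_pitch_mm)))
  invisible(x)
}

#' Elimination mask (excluded low-quality regions)
#'
#' Marks pixels cropped out of the analysis (e.g. movement artifacts).
#' An all-`FALSE` mask is valid and corresponds to an uncropped ("raw") image.
#'
#' @param excluded Logical matrix; `TRUE` marks an excluded pixel.
#' @return An object of class `elimination_mask`.
#' @export
elimination_mask <- function(excluded) {
  if (!is.matrix(excluded) || !is.logical(excluded))
    stop("`excluded` must be a logical matrix", call. = FALSE)
  structure(list(excluded = excluded), class = "elimination_mask")
}

#' @export
print.elimination_mask <- function(x, ...) {
  cat(sprintf("<elimination_mask> %d x %d px, %d excluded\n",
              nrow(x$excluded), ncol(x$excluded), sum(x$excluded)))
  invisible(x)
}

#' Binary non-perfusion segmentation mask
#'
#' @param nonperfusion Logical matrix; `TRUE` marks a non-perfused pixel.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(nonperfusion) {
  if (!is.matrix(nonperfusion) || !is.logical(nonperfusion))
    stop("`nonperfusion` must be a logical matrix", call. = FALSE)
  structure(list(nonperfusion = nonperfusion), class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d px, %d foreground\n",
              nrow(x$nonperfusion), ncol(x$nonperfusion), sum(x$nonperfusion)))
  invisible(x)
}

# Accept either a typed object or a bare matrix; pipeline internals work on
# plain matrices so that small fixtures need not satisfy image-size invariants.
as_pixel_matrix <- function(x) {
  if (inherits(x, "retinal_image")) return(x$pixels)
  if (inherits(x, "variance_map")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a retinal_image, variance_map or numeric matrix", call. = FALSE)
}

as_logical_matrix <- function(x) {
  if (inherits(x, "segmentation_mask")) return(x$nonperfusion)
  if (inherits(x, "elimination_mask")) return(x$excluded)
  if (is.matrix(x) && is.logical(x)) return(x)
  if (is.matrix(x) && is.numeric(x)) return(x > 0)
  stop("expected a mask object or logical matrix", call. = FALSE)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)",
         call. = FALSE))
  if (length(dim(a)) == 3L) {
    # RGB(A) to luminance (Rec. 601 weights); alpha ignored
    a <- 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
  }
  if (length(a) == 0L || nrow(a) == 0L || ncol(a) == 0L)
    stop("zero-area image: ", path, call. = FALSE)
  a
}

#' Read an en-face image from PNG or TIFF
#'
#' 8- and 16-bit rasters are rescaled to the `[0, 255]` working range
#' (16-bit full scale 65535 maps to 255); RGB images are converted to
#' luminance. If a YAML sidecar `<stem>.yaml` with a `pixel_pitch_mm` entry
#' sits next to the image it is picked up automatically.
#'
#' @param path Path to a PNG or TIFF file.
#' @param pixel_pitch_mm Optional pixel pitch override (mm per pixel side).
#' @return A [retinal_image].
#' @export
read_image <- function(path, pixel_pitch_mm = NULL) {
  px <- read_raster(path) * 255
  if (is.null(pixel_pitch_mm)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
    if (file.exists(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      if (!is.null(meta$pixel_pitch_mm))
        pixel_pitch_mm <- as.numeric(meta$pixel_pitch_mm)
    }
  }
  retinal_image(px, pixel_pitch_mm = pixel_pitch_mm)
}

#' Write a binary mask as a lossless 0/255 raster
#'
#' @param mask A [segmentation_mask], [elimination_mask] or logical matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  m <- as_logical_matrix(mask)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  v <- matrix(as.numeric(m), nrow(m), ncol(m))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    stop("unsupported mask format: .", ext, call. = FALSE))
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path Path to a 0/255 PNG or TIFF mask.
#' @return A logical matrix (`TRUE` = foreground).
#' @export
read_mask <- function(path) {
  read_raster(path) * 255 > 127
}

#' Write a grayscale image as an 8-bit raster
#'
#' Intensities are rounded to the nearest 8-bit level, so images with integer
#' intensities round-trip exactly.
#'
#' @param image A [retinal_image] or numeric matrix in `[0, 255]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  px <- as_pixel_matrix(image)
  v <- round(px) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Derive an elimination mask from white paint in a cropped image
#'
#' Cropped-out low-quality areas are conventionally painted pure white.
#' Pixels within `tolerance` of `white_value` are candidate eliminated pixels;
#' only connected white regions (8-connectivity) larger than `min_region_px`
#' are kept, so that isolated saturated vessel pixels are not flagged.
#'
#' @param image A [retinal_image] or numeric matrix.
#' @param white_value Intensity of the elimination paint (default 255).
#' @param tolerance Non-negative intensity tolerance (default 0).
#' @param min_region_px Minimum connected-region area in pixels kept as
#'   eliminated (default 100); regions must be strictly larger.
#' @return An [elimination_mask].
#' @export
derive_elimination_mask <- function(image, white_value = 255, tolerance = 0,
                                    min_region_px = 100) {
  stopifnot(white_value >= 0, white_value <= 255, tolerance >= 0)
  px <- as_pixel_matrix(image)
  cand <- abs(px - white_value) <= tolerance
  if (!any(cand)) return(elimination_mask(cand))
  lab <- label_components(cand, connectivity = 8L)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas > min_region_px)
  elimination_mask(matrix(lab %in% keep, nrow(px), ncol(px)))
}
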