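# Independent brute-force oracles, deliberately written with plain loops /
# base functions so they share no code path with the implementation.

# population variance of the w x w neighborhood of each interior pixel,
# straight from the definition
bf_local_variance_interior <- function(m, w) {
  r <- w %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in (r + 1):(nr - r)) {
    for (j in (r + 1):(nc - r)) {
      win <- as.numeric(m[(i - r):(i + r), (j - r):(j + r)])
      out[i, j] <- mean(win^2) - mean(win)^2
    }
  }
  out
}

# per-pixel confusion tallies with an explicit double loop
bf_confusion <- function(pred, truth, elim = NULL) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (!is.null(elim) && elim[i, j]) next
      if (pred[i, j] && truth[i, j]) tp <- tp + 1L
      else if (pred[i, j]) fp <- fp + 1L
      else if (truth[i, j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# grayscale morphology oracle: min/max over the cross-shaped neighborhood,
# valid only where every probe lands inside the matrix
bf_morph <- function(m, op = c("erode", "dilate"), radius = 2L) {
  op <- match.arg(op)
  f <- if (op == "erode") min else max
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in (radius + 1):(nr - radius)) {
    for (j in (radius + 1):(nc - radius)) {
      probes <- c(m[(i - radius):(i + radius), j], m[i, (j - radius):(j + radius)])
      out[i, j] <- f(probes)
    }
  }
  out
}

bf_closing <- function(m) bf_morph(bf_morph(m, "dilate"), "erode")
bf_opening <- function(m) bf_morph(bf_morph(m, "erode"), "dilate")

# Spearman rho from first principles: Pearson correlation of midranks
bf_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# a small ready-made phantom configuration for fast unit tests
tiny_phantom_config <- function(seed = 1L, n_patches = 2L) {
  phantom_config(size = 128, n_patches = n_patches,
                 patch_radius_range = c(12, 20), seed = seed)
}

tiny_dataset <- function(n = 2L, base_seed = 500L, size = 128) {
  suite <- generate_suite(n, phantom_config(size = size, n_patches = 2,
                                            patch_radius_range = c(12, 20)),
                          base_seed = base_seed)
  lapply(suite, function(s) list(image = s$image, truth = s$truth$nonperfusion,
                                 elim = s$elim$excluded))
}
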