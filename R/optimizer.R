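#' Grid-search specification
#'
#' Defaults reproduce the development-set tuning protocol: intensity threshold
#' 50..100 step 1, variance threshold 10..30 step 0.5, morphology iterations
#' 0..4, and all seven nonempty window-size subsets of \{3, 5, 7\}.
#'
#' @param intensity_range Numeric vector of intensity-threshold values.
#' @param variance_range Numeric vector of variance-threshold values.
#' @param morph_range Integer vector of morphology iteration counts.
#' @param kernel_combos List of kernel-size vectors (subsets of `c(3, 5, 7)`).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(intensity_range = seq(50, 100, by = 1),
                      variance_range = seq(10, 30, by = 0.5),
                      morph_range = 0:4,
                      kernel_combos = list(3, 5, 7, c(3, 5), c(3, 7),
                                           c(5, 7), c(3, 5, 7))) {
  stopifnot(length(intensity_range) >= 1L, length(variance_range) >= 1L,
            length(morph_range) >= 1L, length(kernel_combos) >= 1L)
  if (!all(unlist(kernel_combos) %in% c(3, 5, 7)))
    stop("kernel combos must be subsets of {3, 5, 7}", call. = FALSE)
  structure(list(intensity_range = sort(intensity_range),
                 variance_range = sort(variance_range),
                 morph_range = sort(as.integer(morph_range)),
                 kernel_combos = kernel_combos),
            class = "grid_spec")
}

#' Split image ids into development and test sets
#'
#' Reproducible for a fixed seed. When `groups` is given (e.g. patient ids,
#' both eyes of one patient sharing a group), whole groups are assigned to a
#' side so no group straddles the split.
#'
#' @param ids Character or integer vector of image ids (length >= 2).
#' @param dev_fraction Fraction assigned to the development set, in (0, 1).
#' @param seed Integer seed.
#' @param groups Optional grouping vector aligned with `ids`.
#' @return List with `dev` and `test` id vectors (disjoint, exhaustive).
#' @export
split_dev_test <- function(ids, dev_fraction = 0.7, seed = 1L, groups = NULL) {
  stopifnot(dev_fraction > 0, dev_fraction < 1)
  if (length(ids) < 2L) stop("need at least 2 ids to split", call. = FALSE)
  if (is.null(groups)) groups <- ids
  stopifnot(length(groups) == length(ids))
  target <- round(dev_fraction * length(ids))
  target <- min(max(target, 1L), length(ids) - 1L)
  withr::with_seed(seed, {
    g <- sample(unique(groups))
    dev_groups <- character(0)
    n_dev <- 0L
    for (gr in g) {
      if (n_dev >= target) break
      dev_groups <- c(dev_groups, as.character(gr))
      n_dev <- n_dev + sum(as.character(groups) == as.character(gr))
    }
  })
  in_dev <- as.character(groups) %in% dev_groups
  if (all(in_dev) || !any(in_dev))
    stop("split degenerate: adjust dev_fraction or groups", call. = FALSE)
  list(dev = ids[in_dev], test = ids[!in_dev])
}

# Per-image Dice at every grid point, exploiting the pipeline's structure:
# normalization, the first bilateral pass and the per-kernel variance maps do
# not depend on the thresholds, the second bilateral pass depends only on the
# intensity threshold, morphology only on the iteration count, and the
# binarization + size filter are cheap. Deterministic.
#
# dataset: list of samples, each a list(image, truth, elim = NULL, id = NULL)
evaluate_grid <- function(dataset, grid, base_params = vmseg_params()) {
  stopifnot(inherits(grid, "grid_spec"), length(dataset) >= 1L)
  combo_label <- function(k) paste(sort(k), collapse = "-")
  points <- expand.grid(kernels = vapply(grid$kernel_combos, combo_label, ""),
                        intensity = grid$intensity_range,
                        variance = grid$variance_range,
                        morph = grid$morph_range,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  n_pt <- nrow(points)
  dice_mat <- matrix(NA_real_, length(dataset), n_pt)

  for (i in seq_along(dataset)) {
    smp <- dataset[[i]]
    px <- as_pixel_matrix(smp$image)
    ex <- if (is.null(smp$elim)) NULL else as_logical_matrix(smp$elim)
    truth <- as_logical_matrix(smp$truth)
    norm <- normalize_image(px)
    sm <- bilateral_smooth(norm, base_params$bilateral_diameter,
                           base_params$bilateral_sigma)
    vm_by_k <- lapply(c(3L, 5L, 7L), function(k)
      if (any(vapply(grid$kernel_combos, function(co) k %in% co, logical(1L))))
        local_variance_map(sm, k) else NULL)
    names(vm_by_k) <- c("3", "5", "7")

    for (co in grid$kernel_combos) {
      lab <- combo_label(co)
      vmap <- combine_variance_maps(vm_by_k[as.character(sort(co))])
      for (it in grid$intensity_range) {
        mod <- modify_variance_map(vmap, norm, it)
        if (!is.null(ex)) mod$values[ex] <- 255
        mod <- variance_map(
          as_pixel_matrix(bilateral_smooth(mod$values,
                                           base_params$bilateral_diameter,
                                           base_params$bilateral_sigma)),
          stage = "modified")
        for (mo in grid$morph_range) {
          mor <- morphology_clean(mod, mo, base_params$morph_kernel_size)
          for (vt in grid$variance_range) {
            bin <- binarize(mor, vt)
            out <- fill_and_filter(bin, base_params$size_threshold_px)
            if (!is.null(ex)) out$nonperfusion[ex] <- FALSE
            j <- which(points$kernels == lab & points$intensity == it &
                       points$variance == vt & points$morph == mo)
            dice_mat[i, j] <- dice(confusion(out, truth, ex))
          }
        }
      }
    }
  }
  list(points = points, dice = dice_mat)
}

# deterministic tie-break: smallest variance threshold, then smallest
# intensity threshold, then fewest morphology iterations, then combo order
best_grid_index <- function(points, mean_dice, kernel_combos) {
  combo_rank <- match(points$kernels,
                      vapply(kernel_combos,
                             function(k) paste(sort(k), collapse = "-"), ""))
  ord <- order(-mean_dice, points$variance, points$intensity, points$morph,
               combo_rank)
  ord[1L]
}

marginal_curves <- function(points, mean_dice, best) {
  curves <- list()
  for (par in c("intensity", "variance", "morph")) {
    others <- setdiff(c("kernels", "intensity", "variance", "morph"), par)
    sel <- rep(TRUE, nrow(points))
    for (o in others) sel <- sel & points[[o]] == points[[o]][best]
    curves[[par]] <- data.frame(value = points[[par]][sel],
                                mean_dice = mean_dice[sel])
    curves[[par]] <- curves[[par]][order(curves[[par]]$value), ]
    rownames(curves[[par]]) <- NULL
  }
  curves
}

#' Exhaustive grid search for the optimal pipeline parameters
#'
#' Evaluates the mean Dice coefficient over the dataset at every point of the
#' Cartesian grid and returns the maximizer. Ties are broken toward the
#' smallest variance threshold, then the smallest intensity threshold, then
#' the fewest morphology iterations. Marginal mean-Dice curves (each parameter
#' varied with the others held at the optimum) are reported for plotting.
#'
#' @param dataset List of samples; each sample is a list with elements
#'   `image`, `truth`, and optionally `elim` and `id`.
#' @param grid A [grid_spec].
#' @param base_params A [vmseg_params] supplying the non-searched parameters
#'   (bilateral filter, size threshold).
#' @return An object of class `vmseg_opt`: `best_params` ([vmseg_params]),
#'   `best_mean_dice`, `marginals` (per-parameter data.frames), and `table`
#'   (one row per grid point with its mean Dice).
#' @export
grid_search <- function(dataset, grid = grid_spec(),
                        base_params = vmseg_params()) {
  if (length(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  ev <- evaluate_grid(dataset, grid, base_params)
  mean_dice <- colMeans(ev$dice)
  best <- best_grid_index(ev$points, mean_dice, grid$kernel_combos)
  bp <- vmseg_params(
    kernel_sizes = as.integer(strsplit(ev$points$kernels[best], "-")[[1L]]),
    variance_threshold = ev$points$variance[best],
    intensity_threshold = ev$points$intensity[best],
    morph_iterations = ev$points$morph[best],
    size_threshold_px = base_params$size_threshold_px,
    bilateral_diameter = base_params$bilateral_diameter,
    bilateral_sigma = base_params$bilateral_sigma,
    morph_kernel_size = base_params$morph_kernel_size)
  table <- cbind(ev$points, mean_dice = mean_dice)
  structure(list(best_params = bp,
                 best_mean_dice = mean_dice[best],
                 marginals = marginal_curves(ev$points, mean_dice, best),
                 table = table),
            class = "vmseg_opt")
}

#' @export
print.vmseg_opt <- function(x, ...) {
  cat(sprintf("<vmseg_opt> best mean Dice %.4f at\n", x$best_mean_dice))
  print(x$best_params)
  invisible(x)
}

#' Robustness of the parameter optimum under development-set resampling
#'
#' Draws `n_repeats` random subsets (a fraction `subset_fraction` of the
#' images, without replacement), reruns the grid search on each, and reports
#' the mean and sd of each optimal parameter across repeats. Because the grid
#' search is deterministic per image, the per-image Dice table is computed
#' once and each repeat reduces it over its subset — identical results to
#' rerunning the full search per subset.
#'
#' @param dataset As in [grid_search()].
#' @param grid A [grid_spec].
#' @param n_repeats Number of resampled subsets (>= 2).
#' @param subset_fraction Fraction of images per subset, in (0, 1]; each
#'   subset must contain at least one image.
#' @param seed Integer seed for the resampling.
#' @param base_params A [vmseg_params] for the non-searched parameters.
#' @return List of class `vmseg_robustness`: `optima` (one row per repeat),
#'   `summary` (mean and sd per parameter), `curves` (per-repeat marginal
#'   curves), and `seed`.
#' @export
robustness_analysis <- function(dataset, grid = grid_spec(), n_repeats = 10,
                                subset_fraction = 0.7, seed = 1L,
                                base_params = vmseg_params()) {
  stopifnot(n_repeats >= 2, subset_fraction > 0, subset_fraction <= 1)
  n <- length(dataset)
  m <- floor(subset_fraction * n)
  if (m < 1L) stop("subset too small: fewer than 1 image", call. = FALSE)
  ev <- evaluate_grid(dataset, grid, base_params)
  subsets <- withr::with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) sort(sample(n, m)))
  })
  rows <- vector("list", n_repeats)
  curves <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    md <- colMeans(ev$dice[subsets[[r]], , drop = FALSE])
    best <- best_grid_index(ev$points, md, grid$kernel_combos)
    rows[[r]] <- data.frame(repeat_id = r,
                            kernels = ev$points$kernels[best],
                            intensity = ev$points$intensity[best],
                            variance = ev$points$variance[best],
                            morph = ev$points$morph[best],
                            mean_dice = md[best],
                            stringsAsFactors = FALSE)
    curves[[r]] <- marginal_curves(ev$points, md, best)
  }
  optima <- do.call(rbind, rows)
  summ <- data.frame(
    parameter = c("intensity_threshold", "variance_threshold",
                  "morph_iterations"),
    mean = c(mean(optima$intensity), mean(optima$variance),
             mean(optima$morph)),
    sd = c(stats::sd(optima$intensity), stats::sd(optima$variance),
           stats::sd(optima$morph)))
  structure(list(optima = optima, summary = summ, curves = curves,
                 seed = seed),
            class = "vmseg_robustness")
}

#' @export
print.vmseg_robustness <- function(x, ...) {
  cat(sprintf("<vmseg_robustness> %d repeats (seed %d)\n",
              nrow(x$optima), x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
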