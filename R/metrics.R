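#' Pixelwise confusion counts between two masks
#'
#' Counts are taken over the evaluable region only: pixels under the
#' elimination mask are dropped before tallying, mirroring their exclusion
#' from the NPI denominator.
#'
#' @param pred,truth [segmentation_mask] objects or logical matrices.
#' @param elim Optional [elimination_mask] or logical matrix.
#' @return A list of class `confusion_counts` with integer fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(pred, truth, elim = NULL) {
  p <- as_logical_matrix(pred)
  t <- as_logical_matrix(truth)
  if (!identical(dim(p), dim(t)))
    stop("prediction and truth shapes differ", call. = FALSE)
  if (!is.null(elim)) {
    e <- as_logical_matrix(elim)
    if (!identical(dim(e), dim(p)))
      stop("elimination mask shape differs", call. = FALSE)
    keep <- !e
    p <- p[keep]; t <- t[keep]
  }
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' Dice overlap coefficient
#'
#' `2 TP / (2 TP + FP + FN)`. When both masks are empty over the evaluable
#' region (TP = FP = FN = 0) the coefficient is defined as 1 — perfect
#' agreement on absence.
#'
#' @param counts A `confusion_counts` object from [confusion()].
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) return(1)
  2 * counts$TP / den
}

#' Non-perfusion index
#'
#' Non-perfused area divided by the analyzable area:
#' `NPI = area_np / (area_total - area_elim)`.
#'
#' @param area_np Non-perfused pixel (or mm^2) count.
#' @param area_total Total image area in the same unit.
#' @param area_elim Eliminated (excluded) area in the same unit.
#' @return NPI in `[0, 1]`.
#' @export
npi <- function(area_np, area_total, area_elim = 0) {
  den <- area_total - area_elim
  if (den <= 0)
    stop("analyzable area must be positive (area_total > area_elim)",
         call. = FALSE)
  if (area_np < 0 || area_np > den)
    stop("area_np must lie within [0, area_total - area_elim]", call. = FALSE)
  area_np / den
}

#' Non-perfusion index of a mask pair
#'
#' @param mask A [segmentation_mask] or logical matrix.
#' @param elim Optional [elimination_mask] or logical matrix.
#' @return NPI in `[0, 1]`.
#' @export
npi_from_mask <- function(mask, elim = NULL) {
  m <- as_logical_matrix(mask)
  e_area <- if (is.null(elim)) 0 else sum(as_logical_matrix(elim))
  npi(sum(m), length(m), e_area)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Midranks for ties; p-value from the asymptotic t distribution.
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither constant.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: rank correlation undefined", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` with limits of agreement `mean(d) +/- 1.96 sd(d)`
#' (sample sd); points whose difference falls outside the limits are flagged
#' as outliers. The pairwise means `(a + b) / 2` are returned as the
#' conventional x-axis for plotting.
#'
#' @param a,b Numeric vectors of equal length, at least 3.
#' @param ids Optional labels (defaults to indices).
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `outlier_ids`,
#'   `differences` and `means`.
#' @export
bland_altman <- function(a, b, ids = NULL) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (is.null(ids)) ids <- seq_along(a)
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  lo <- md - 1.96 * s
  hi <- md + 1.96 * s
  out <- ids[d < lo | d > hi]
  list(mean_diff = md, loa_low = lo, loa_high = hi,
       outlier_ids = out, differences = d, means = (a + b) / 2)
}

#' Evaluate predicted masks against ground truth over a batch
#'
#' @param preds,truths Lists of masks (or logical matrices), same length.
#' @param elims Optional list of elimination masks (or `NULL` entries).
#' @param ids Image labels; defaults to indices.
#' @return A data.frame with one row per image: `id`, `dice`, `npi_estimated`,
#'   `npi_ground_truth`, `area_nonperfusion`, `area_total`, `area_eliminated`.
#' @export
evaluate_batch <- function(preds, truths, elims = NULL, ids = NULL) {
  n <- length(preds)
  stopifnot(length(truths) == n, n >= 1L)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(elims)) elims <- vector("list", n)
  rows <- lapply(seq_len(n), function(i) {
    p <- as_logical_matrix(preds[[i]])
    t <- as_logical_matrix(truths[[i]])
    e <- if (is.null(elims[[i]])) NULL else as_logical_matrix(elims[[i]])
    cc <- confusion(p, t, e)
    e_area <- if (is.null(e)) 0L else sum(e)
    data.frame(id = ids[[i]],
               dice = dice(cc),
               npi_estimated = npi_from_mask(p, e),
               npi_ground_truth = npi_from_mask(t, e),
               area_nonperfusion = sum(p & !isTRUE_mat(e, dim(p))),
               area_total = length(p),
               area_eliminated = e_area,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# helper: elimination as matrix of FALSE when absent
isTRUE_mat <- function(e, d) {
  if (is.null(e)) matrix(FALSE, d[1L], d[2L]) else e
}

#' Summarize a batch evaluation
#'
#' Mean and sd of the Dice coefficients, the Spearman correlation between
#' estimated and ground-truth NPI, and Bland-Altman outliers of the NPI pairs.
#'
#' @param records Data.frame from [evaluate_batch()].
#' @return List with `mean_dice`, `sd_dice`, `npi_spearman` (rho, p) and
#'   `bland_altman`.
#' @export
summarize_evaluation <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  npi_sp <- if (nrow(records) >= 3L &&
                stats::sd(records$npi_estimated) > 0 &&
                stats::sd(records$npi_ground_truth) > 0)
    spearman_cor(records$npi_estimated, records$npi_ground_truth)
  else list(rho = NA_real_, p = NA_real_)
  ba <- if (nrow(records) >= 3L)
    bland_altman(records$npi_estimated, records$npi_ground_truth,
                 ids = records$id)
  else NULL
  list(mean_dice = mean(records$dice),
       sd_dice = stats::sd(records$dice),
       npi_spearman = npi_sp,
       bland_altman = ba)
}
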