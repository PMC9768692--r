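#' Segmentation scores of a recovered map against a target
#'
#' Confusion-matrix scores over all grid cells: Jaccard index, Dice
#' score, Matthews correlation coefficient, symmetric uncertainty
#' (`2 I(A;B) / (H(A) + H(B))` with base-2 empirical entropies of the
#' binary cell labels), and the modified Hausdorff distance between the
#' two cell sets — `max` of the two directed mean nearest-neighbour
#' distances between cell centres — expressed as a fraction of the grid
#' diagonal. An empty recovered map scores 0 on the overlap metrics and
#' `NA` on the Hausdorff fraction.
#'
#' @param recovered,target Logical matrices on the same grid (a
#'   [threshold_map()] result is accepted for `recovered`).
#' @param grid A [grid_spec()] (used for cell centres and the diagonal);
#'   defaults to a unit-cell grid of the maps' dimensions.
#' @return A one-row data frame: `jaccard`, `dice`, `mcc`,
#'   `symmetric_uncertainty`, `mhd_fraction`.
#' @export
segmentation_scores <- function(recovered, target, grid = NULL) {
  if (inherits(recovered, "significance_map")) recovered <- recovered$significant
  if (!all(dim(recovered) == dim(target)))
    stop("recovered and target maps are on mismatched grids")
  if (!any(target)) stop("target map is empty")
  if (is.null(grid)) grid <- grid_spec(ncol(target), nrow(target))

  a <- as.vector(recovered); b <- as.vector(target)
  tp <- as.numeric(sum(a & b)); fp <- as.numeric(sum(a & !b))
  fn <- as.numeric(sum(!a & b)); tn <- as.numeric(sum(!a & !b))

  jaccard <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
  dice <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)

  n <- length(a)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ha <- h(c(tp + fp, fn + tn) / n)
  hb <- h(c(tp + fn, fp + tn) / n)
  hab <- h(c(tp, fp, fn, tn) / n)
  su <- if (ha + hb == 0) 0 else 2 * (ha + hb - hab) / (ha + hb)

  if (!any(a)) {
    mhd_fraction <- NA_real_
  } else {
    centers <- cell_centers(grid)
    pa <- centers[a, , drop = FALSE]
    pb <- centers[b, , drop = FALSE]
    mhd <- max(mean(nn_min_dist_cpp(pa, pb)), mean(nn_min_dist_cpp(pb, pa)))
    mhd_fraction <- mhd / grid_diagonal(grid)
  }
  data.frame(jaccard = jaccard, dice = dice, mcc = mcc,
             symmetric_uncertainty = su, mhd_fraction = mhd_fraction)
}

#' Coverage score of a set of per-condition maps
#'
#' The number of grid cells significant for exactly one of the spatial
#' conditions — overlap between conditions is ignored. Used to pick the
#' smoothing scale.
#'
#' @param maps List of [threshold_map()] results (or logical matrices)
#'   on one grid.
#' @return Integer count.
#' @export
coverage_score <- function(maps) {
  sig <- lapply(maps, function(m) if (inherits(m, "significance_map")) m$significant else m)
  dims <- vapply(sig, dim, integer(2))
  if (any(dims != dims[, 1])) stop("maps are on mismatched grids")
  counts <- Reduce(`+`, sig)
  sum(counts == 1L)
}

#' Select the smoothing scale by coverage
#'
#' Picks the scale with the highest coverage score; ties are broken by
#' choosing the smallest scale.
#'
#' @param scores_by_scale Named numeric vector (names = scales) or a
#'   numeric vector with a parallel `scales` argument.
#' @param scales Optional numeric vector of scales.
#' @return The selected scale (numeric).
#' @export
select_scale <- function(scores_by_scale, scales = NULL) {
  if (is.null(scales)) scales <- as.numeric(names(scores_by_scale))
  if (!length(scores_by_scale)) stop("no scores supplied")
  if (any(is.na(scales))) stop("scales could not be determined")
  ord <- order(scales)
  scales <- scales[ord]; s <- scores_by_scale[ord]
  scales[which.max(s)] # which.max returns the first (smallest) maximiser
}

#' Standardize an external prediction raster into a significance map
#'
#' Converts a spatial prediction (e.g. a kriging mean) and its positional
#' variance into a z map against a null mean, and thresholds the z map at
#' the upper-tail critical value of the standard normal:
#' `z = (pred - mu_null) / sqrt(pred_var)`, significant iff
#' `z > qnorm(1 - alpha)`. Cells with non-positive variance are absent.
#'
#' @param pred Prediction raster (matrix).
#' @param pred_var Prediction variance raster (matrix, same shape).
#' @param mu_null Null mean (default 0.5, the uninformative value for a
#'   binary outcome).
#' @param alpha Upper-tail significance level (default 0.05,
#'   uncorrected).
#' @return List with `z` (matrix, `NA` where undefined) and
#'   `significant` (logical matrix).
#' @export
standardize_prediction <- function(pred, pred_var, mu_null = 0.5, alpha = 0.05) {
  if (!all(dim(pred) == dim(pred_var))) stop("pred and pred_var shapes differ")
  ok <- is.finite(pred_var) & pred_var > 0 & is.finite(pred)
  z <- (pred - mu_null) / sqrt(pred_var)
  z[!ok] <- NA_real_
  crit <- stats::qnorm(1 - alpha)
  sig <- !is.na(z) & z > crit
  list(z = z, significant = sig)
}
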