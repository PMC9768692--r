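#' Unit-normalize residual fields
#'
#' Scales the residual vector at each cell to unit Euclidean norm:
#' `u_i = r_i / sqrt(sum_i r_i^2)`. The normalized residuals carry the
#' spatial autocorrelation of the error fields and are the input to
#' smoothness estimation. Cells with zero residual norm are `NA`.
#'
#' @param fit A [fit_mass_univariate()] result.
#' @return An `N x n_cells` matrix of normalized residuals.
#' @export
standardize_residuals <- function(fit) {
  r <- fit$residuals
  norm2 <- colSums(r^2)
  bad <- !fit$mask | fit$degenerate | !is.finite(norm2) | norm2 <= 0
  u <- sweep(r, 2L, sqrt(norm2), "/")
  u[, bad] <- NA_real_
  u
}

#' Estimate residual field smoothness (FWHM)
#'
#' Per axis d, `lambda_d` is the mean over masked interior cells of the
#' sum over observations of squared forward differences of the normalized
#' residuals; the full width at half maximum of the equivalent Gaussian
#' smoothing kernel is `fwhm_d = sqrt(4 log 2 / lambda_d)`, in cell
#' units. For a field produced by smoothing white noise with a Gaussian
#' kernel this recovers the kernel's FWHM.
#'
#' @param u Normalized residual stack from [standardize_residuals()].
#' @param grid A [grid_spec()].
#' @param mask Optional logical matrix; cells with undefined residuals
#'   are dropped automatically.
#' @return Object of class `smoothness_estimate`: `fwhm_x`, `fwhm_y`
#'   (cell units) and the per-axis `lambda` values.
#' @export
estimate_fwhm <- function(u, grid, mask = NULL) {
  m <- n_cells(grid)
  if (ncol(u) != m) stop("residual stack does not match the grid")
  valid <- !is.na(u[1L, ]) # columns are all-NA or fully defined
  if (!is.null(mask)) valid <- valid & as.vector(mask)
  vm <- matrix(valid, grid$n_rows, grid$n_cols)
  if (max(rowSums(vm)) < 2L || max(colSums(vm)) < 2L)
    stop("mask must span at least 2 cells along each axis")

  nr <- grid$n_rows; nc <- grid$n_cols
  idx <- matrix(seq_len(m), nr, nc)

  # x axis: cell (r, c) and (r, c + 1)
  a <- as.vector(idx[, -nc, drop = FALSE]); b <- as.vector(idx[, -1L, drop = FALSE])
  ok <- valid[a] & valid[b]
  if (!any(ok)) stop("degenerate smoothness: no valid x-adjacent cell pairs")
  lambda_x <- mean(colSums((u[, b[ok], drop = FALSE] - u[, a[ok], drop = FALSE])^2))

  # y axis: cell (r, c) and (r + 1, c)
  a <- as.vector(idx[-nr, , drop = FALSE]); b <- as.vector(idx[-1L, , drop = FALSE])
  ok <- valid[a] & valid[b]
  if (!any(ok)) stop("degenerate smoothness: no valid y-adjacent cell pairs")
  lambda_y <- mean(colSums((u[, b[ok], drop = FALSE] - u[, a[ok], drop = FALSE])^2))

  if (lambda_x <= 0 || lambda_y <= 0)
    stop("degenerate smoothness: residual fields are flat along an axis")
  structure(list(fwhm_x = sqrt(4 * log(2) / lambda_x),
                 fwhm_y = sqrt(4 * log(2) / lambda_y),
                 lambda = c(x = lambda_x, y = lambda_y)),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM = (%.3f, %.3f) cells\n",
              x$fwhm_x, x$fwhm_y))
  invisible(x)
}

#' Resel counts of a search region
#'
#' Expresses the masked search region in resolution elements (resels) of
#' the estimated smoothness. For a full W x H rectangle: `R0 = 1`,
#' `R1 = W / fwhm_x + H / fwhm_y`, `R2 = W * H / (fwhm_x * fwhm_y)`. For
#' an irregular mask, R2 scales the masked area, R1 takes half the mask
#' boundary length split by axis, and R0 is the Euler characteristic of
#' the mask.
#'
#' @param mask Logical matrix (rows index y).
#' @param fwhm_x,fwhm_y Smoothness in cell units.
#' @return Numeric vector `c(R0, R1, R2)`.
#' @export
resel_counts <- function(mask, fwhm_x, fwhm_y) {
  mask <- as.matrix(mask)
  if (!any(mask)) stop("mask is empty")
  nr <- nrow(mask); nc <- ncol(mask)
  area <- sum(mask)

  # boundary edge counts by orientation: an edge of a masked cell lies on
  # the boundary iff the neighbour across it is outside the mask/grid
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  # horizontal edges (running along x): neighbours above/below (y axis)
  n_bx <- sum(core & !pad[1:nr, 2:(nc + 1L)]) + sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)])
  # vertical edges (running along y): neighbours left/right (x axis)
  n_by <- sum(core & !pad[2:(nr + 1L), 1:nc]) + sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])

  # Euler characteristic of the cell complex: vertices - edges + faces
  which_cells <- which(mask, arr.ind = TRUE)
  r <- which_cells[, 1L]; cc <- which_cells[, 2L]
  vkey <- function(rr, ccc) (rr - 1) * (nc + 1) + (ccc - 1)
  verts <- unique(c(vkey(r, cc), vkey(r + 1L, cc), vkey(r, cc + 1L), vkey(r + 1L, cc + 1L)))
  # horizontal edges keyed by their left vertex, vertical by their bottom vertex
  hedges <- unique(c(vkey(r, cc), vkey(r + 1L, cc)))
  vedges <- unique(c(vkey(r, cc), vkey(r, cc + 1L)))
  chi <- length(verts) - (length(hedges) + length(vedges)) + area

  c(R0 = chi,
    R1 = (n_bx / 2) / fwhm_x + (n_by / 2) / fwhm_y,
    R2 = area / (fwhm_x * fwhm_y))
}

#' Euler characteristic densities of a t field
#'
#' Per-resel contribution of dimension d to the expected Euler
#' characteristic of the excursion set of a t field above `t`.
#'
#' @param t Threshold (scalar or vector).
#' @param nu Residual degrees of freedom (>= 1).
#' @param d Dimension: 0, 1 or 2.
#' @return The EC density value(s).
#' @export
ec_density_t <- function(t, nu, d) {
  if (nu < 1) stop("nu must be >= 1")
  if (!(d %in% c(0L, 1L, 2L))) stop("d must be 0, 1 or 2")
  if (d == 0L) return(stats::pt(t, df = nu, lower.tail = FALSE))
  base <- (1 + t^2 / nu)^(-(nu - 1) / 2)
  if (d == 1L) return(sqrt(4 * log(2)) / (2 * pi) * base)
  (4 * log(2)) / (2 * pi)^(3 / 2) *
    exp(lgamma((nu + 1) / 2) - lgamma(nu / 2)) / sqrt(nu / 2) * t * base
}

expected_ec <- function(t, nu, resels) {
  resels[[1]] * ec_density_t(t, nu, 0L) +
    resels[[2]] * ec_density_t(t, nu, 1L) +
    resels[[3]] * ec_density_t(t, nu, 2L)
}

#' Voxel-level FWE-corrected t threshold
#'
#' Solves `sum_d R_d rho_d(t) = a` for t by monotone root finding, where
#' `a = alpha` (one-tailed) or `alpha / 2` (two-tailed), and returns the
#' smaller of the random-field-theory threshold and the Bonferroni
#' threshold over the masked cells.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param nu Residual degrees of freedom.
#' @param resels `c(R0, R1, R2)` from [resel_counts()].
#' @param n_masked_cells Number of cells searched (Bonferroni).
#' @param tails `"one"` or `"two"`.
#' @return The critical t value.
#' @export
fwe_threshold <- function(alpha, nu, resels, n_masked_cells,
                          tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (length(resels) != 3L || any(!is.finite(resels)) || resels[[3]] < 0)
    stop("resels must be a finite triple")
  a <- if (tails == "two") alpha / 2 else alpha
  f <- function(t) expected_ec(t, nu, resels) - a
  lo <- 1e-6; hi <- 100
  if (f(hi) > 0) stop("FWE threshold root is not bracketed (pathological resels)")
  if (f(lo) < 0) {
    t_rft <- lo
  } else {
    t_rft <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
    if (abs(f(t_rft)) > 1e-10)
      t_rft <- stats::uniroot(f, c(max(lo, t_rft - 1), min(hi, t_rft + 1)),
                              tol = .Machine$double.eps)$root
  }
  t_bonf <- stats::qt(a / n_masked_cells, df = nu, lower.tail = FALSE)
  min(t_rft, t_bonf)
}

#' Threshold a t map into a significance map
#'
#' @param t_map Matrix of t statistics (`NA` = absent).
#' @param threshold_t Positive critical value.
#' @param tails `"one"` (significant iff `t >= threshold_t`) or `"two"`
#'   (iff `|t| >= threshold_t`).
#' @param mask Optional logical matrix; cells outside are never
#'   significant.
#' @param alpha Recorded alongside for reporting.
#' @return Object of class `significance_map`: `significant` and `mask`
#'   logical matrices plus `threshold_t`, `alpha`, `tails`.
#' @export
threshold_map <- function(t_map, threshold_t, tails = c("one", "two"),
                          mask = NULL, alpha = NA_real_) {
  tails <- match.arg(tails)
  if (!is.finite(threshold_t) || threshold_t <= 0)
    stop("threshold_t must be positive")
  if (is.null(mask)) mask <- !is.na(t_map)
  mask <- mask & !is.na(t_map)
  sig <- if (tails == "one") t_map >= threshold_t else abs(t_map) >= threshold_t
  sig[is.na(sig)] <- FALSE
  sig <- sig & mask
  structure(list(significant = sig, mask = mask, threshold_t = threshold_t,
                 alpha = alpha, tails = tails),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("<significance_map> %d significant / %d masked cells (t >= %.3f, %s-tailed)\n",
              sum(x$significant), sum(x$mask), x$threshold_t, x$tails))
  invisible(x)
}

#' Conjunction of significance maps
#'
#' The intersection of two or more thresholded maps: a cell is in the
#' conjunction iff it is significant in every input map.
#'
#' @param maps List of [threshold_map()] results (or logical matrices)
#'   sharing one grid.
#' @return A logical matrix.
#' @export
conjunction <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  sig <- lapply(maps, function(m) if (inherits(m, "significance_map")) m$significant else m)
  dims <- vapply(sig, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("maps are on mismatched grids")
  Reduce(`&`, sig)
}
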