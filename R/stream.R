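# Streaming mass-univariate fit + residual smoothness.
#
# Algebraically identical to fit_mass_univariate() followed by
# standardize_residuals() and estimate_fwhm(), but accumulates X'Y, the
# per-cell response sum of squares and the inner products of responses
# at axis-adjacent cells over observation chunks, so the N x n_cells
# response matrix is never held in memory. Used by the experiment
# drivers, where N x n_cells can run to hundreds of millions of entries.
#
# Identities used (OLS via the pseudoinverse, P = X'Y, B = (X'X)^- P):
#   r_a'r_b = (Y'Y)_ab - P_a'B_b - B_a'P_b + B_a'(X'X)B_b
# for any two cells a, b (a = b gives the residual sum of squares), and
#   sum_i (u_ib - u_ia)^2 = 2 - 2 r_a'r_b / (|r_a||r_b|)
# for unit-normalized residuals, which yields the per-axis lambda.
stream_fit_smoothness <- function(X, obs, kernel, grid,
                                  chunk_cells = 6e7) {
  n <- nrow(X)
  m <- n_cells(grid)
  nr <- grid$n_rows; nc <- grid$n_cols
  rk <- qr(X)$rank
  nu <- n - rk
  if (nu < 1L) stop("residual degrees of freedom nu = N - rank(X) must be >= 1")
  XtX <- crossprod(X)
  XtX_pinv <- MASS::ginv(XtX)

  idx <- matrix(seq_len(m), nr, nc)
  ax <- as.vector(idx[, -nc]); bx <- as.vector(idx[, -1L])
  ay <- as.vector(idx[-nr, ]); by <- as.vector(idx[-1L, ])

  P <- matrix(0, ncol(X), m)
  d0 <- numeric(m)
  dx <- numeric(length(ax))
  dy <- numeric(length(ay))
  chunk <- max(1L, min(n, floor(chunk_cells / m)))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    Yc <- rasterize_points_cpp(obs$locations[rows, 1L], obs$locations[rows, 2L],
                               kernel$sigma, kernel$truncation_radius,
                               grid$origin_x, grid$origin_y, grid$cell_size,
                               nr, nc)
    P <- P + crossprod(X[rows, , drop = FALSE], Yc)
    cp <- cell_cross_products_cpp(Yc, nr, nc)
    d0 <- d0 + cp$d0
    dx <- dx + cp$dx
    dy <- dy + cp$dy
    rm(Yc, cp)
  }
  beta <- XtX_pinv %*% P
  pb <- colSums(P * beta)
  bxtxb <- colSums(beta * (XtX %*% beta))
  rss <- pmax(d0 - 2 * pb + bxtxb, 0)
  sigma2 <- rss / nu
  degenerate <- sigma2 <= .Machine$double.eps * d0 / nu

  cross <- function(a, b, dab) {
    dab - colSums(P[, a, drop = FALSE] * beta[, b, drop = FALSE]) -
      colSums(beta[, a, drop = FALSE] * P[, b, drop = FALSE]) +
      colSums(beta[, a, drop = FALSE] * (XtX %*% beta[, b, drop = FALSE]))
  }
  lambda_axis <- function(a, b, dab) {
    ok <- !degenerate[a] & !degenerate[b]
    if (!any(ok)) stop("degenerate smoothness: no valid adjacent cell pairs")
    r_ab <- cross(a[ok], b[ok], dab[ok])
    mean(pmax(2 - 2 * r_ab / sqrt(rss[a[ok]] * rss[b[ok]]), 0))
  }
  lambda_x <- lambda_axis(ax, bx, dx)
  lambda_y <- lambda_axis(ay, by, dy)
  if (lambda_x <= 0 || lambda_y <= 0)
    stop("degenerate smoothness: residual fields are flat along an axis")

  fit <- structure(
    list(beta = beta, sigma2 = sigma2, residuals = NULL, nu = nu, rank = rk,
         XtX_pinv = XtX_pinv, X = X,
         term_names = colnames(X), mask = rep(TRUE, m),
         degenerate = degenerate, grid = grid),
    class = "mu_fit")
  rownames(fit$beta) <- colnames(X)
  smoothness <- structure(
    list(fwhm_x = sqrt(4 * log(2) / lambda_x),
         fwhm_y = sqrt(4 * log(2) / lambda_y),
         lambda = c(x = lambda_x, y = lambda_y)),
    class = "smoothness_estimate")
  list(fit = fit, smoothness = smoothness)
}
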