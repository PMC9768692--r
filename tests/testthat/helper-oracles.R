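# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Mass of an isotropic bivariate Gaussian inside a disc of given radius,
# by 2D Riemann sum over a fine square lattice.
disc_mass_riemann <- function(sigma, radius, step = sigma / 50) {
  g <- seq(-radius, radius, by = step)
  xy <- expand.grid(x = g, y = g)
  inside <- xy$x^2 + xy$y^2 <= radius^2
  dens <- exp(-(xy$x^2 + xy$y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  sum(dens[inside]) * step^2
}

# Per-cell textbook OLS solve (QR via lm.fit), returning beta, sigma2 and
# t statistics for a contrast.
brute_force_ols <- function(X, Y, contrast = NULL) {
  q <- ncol(X)
  rank <- qr(X)$rank
  nu <- nrow(X) - rank
  beta <- matrix(NA_real_, q, ncol(Y))
  sigma2 <- numeric(ncol(Y))
  for (m in seq_len(ncol(Y))) {
    f <- lm.fit(X, Y[, m])
    b <- f$coefficients
    b[is.na(b)] <- 0
    beta[, m] <- b
    sigma2[m] <- sum(f$residuals^2) / nu
  }
  out <- list(beta = beta, sigma2 = sigma2, nu = nu)
  if (!is.null(contrast)) {
    cvar <- drop(t(contrast) %*% solve(crossprod(X)) %*% contrast)
    out$t <- drop(crossprod(contrast, beta)) / sqrt(sigma2 * cvar)
  }
  out
}

# Smooth a matrix with a (truncated, renormalised) separable Gaussian
# kernel of the given FWHM, via explicit 1D convolution matrices.
gaussian_smooth_matrix <- function(mat, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  conv1d <- function(n) {
    centers <- seq_len(n)
    K <- outer(centers, centers, function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
    K / rowSums(K)
  }
  Kr <- conv1d(nrow(mat))
  Kc <- conv1d(ncol(mat))
  Kr %*% mat %*% t(Kc)
}

# Confusion counts recomputed independently with table().
brute_confusion <- function(a, b) {
  tab <- table(factor(as.vector(a), c(FALSE, TRUE)),
               factor(as.vector(b), c(FALSE, TRUE)))
  c(tp = as.numeric(tab["TRUE", "TRUE"]), fp = as.numeric(tab["TRUE", "FALSE"]),
    fn = as.numeric(tab["FALSE", "TRUE"]), tn = as.numeric(tab["FALSE", "FALSE"]))
}

# Bisection root finder, independent of stats::uniroot.
bisect <- function(f, lo, hi, tol = 1e-12, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
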