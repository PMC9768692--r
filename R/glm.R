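#' One-hot encode spatial conditions
#'
#' Thresholds every observed variable at `threshold` (values strictly
#' greater than the threshold count as 1) and maps each observation to its
#' spatial condition — the P-tuple of indicators. Conditions are returned
#' as K mutually exclusive dummy variables, exactly one of which equals 1
#' per observation: K = 2 for P = 1 (ordering 0, 1) and K = 4 for P = 2
#' (ordering (0,0), (1,0), (0,1), (1,1)).
#'
#' @param obs An [observation_table()] with 1 or 2 numeric variables.
#' @param threshold Threshold applied to every variable (default 0.5).
#' @return An [observation_table()] whose values are the K dummy columns;
#'   the condition labels are kept as column names (`cond_<pattern>`).
#' @export
one_hot_conditions <- function(obs, threshold = 0.5) {
  p <- ncol(obs$values)
  if (p > 2L) stop("one-hot conditions are defined for 1 or 2 variables")
  z <- obs$values > threshold
  if (p == 1L) {
    idx <- as.integer(z[, 1L]) + 1L
    labels <- c("cond_0", "cond_1")
  } else {
    # ordering (0,0), (1,0), (0,1), (1,1)
    idx <- 1L + as.integer(z[, 1L]) + 2L * as.integer(z[, 2L])
    labels <- c("cond_00", "cond_10", "cond_01", "cond_11")
  }
  dummies <- matrix(0, nrow = nrow(z), ncol = length(labels),
                    dimnames = list(NULL, labels))
  dummies[cbind(seq_along(idx), idx)] <- 1
  observation_table(obs$locations, dummies, labels)
}

#' Specify a design
#'
#' @param terms Character vector of model terms, in order. Each term is a
#'   variable name or an interaction written `"a*b"` (element-wise product
#'   of the raw values).
#' @param intercept Should a leading column of ones be included?
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(terms, intercept = TRUE) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate terms in design")
  structure(list(terms = terms, intercept = isTRUE(intercept)),
            class = "design_spec")
}

#' Build the design matrix
#'
#' @param obs An [observation_table()].
#' @param spec A [design_spec()]; interaction terms (`"a*b"`) become
#'   element-wise products of their factors.
#' @return An object of class `design_matrix`: list with `X` (N x Q),
#'   `term_names` and `rank`.
#' @export
build_design <- function(obs, spec) {
  vals <- obs$values
  cols <- list()
  nm <- character(0)
  if (spec$intercept) {
    cols <- c(cols, list(rep(1, nrow(vals))))
    nm <- "intercept"
  }
  for (tm in spec$terms) {
    parts <- strsplit(tm, "*", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    missing <- setdiff(parts, colnames(vals))
    if (length(missing))
      stop(sprintf("design references unknown variable(s): %s",
                   paste(missing, collapse = ", ")))
    col <- Reduce(`*`, lapply(parts, function(v) vals[, v]))
    cols <- c(cols, list(col))
    nm <- c(nm, tm)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  if (any(!is.finite(X))) stop("design matrix contains non-finite values")
  rk <- qr(X)$rank
  if (spec$intercept && rk < ncol(X)) {
    # intercept + a full set of mutually exclusive dummies is the classic cause
    dummy_like <- vapply(seq_len(ncol(X))[-1L],
                         function(q) all(X[, q] %in% c(0, 1)), logical(1))
    if (all(dummy_like))
      stop(paste("design is rank deficient: a full one-hot encoding cannot be",
                 "combined with an intercept; drop the intercept",
                 "(design_spec(..., intercept = FALSE))"))
  }
  structure(list(X = X, term_names = nm, rank = rk), class = "design_matrix")
}

design_from_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, term_names = colnames(X), rank = qr(X)$rank),
            class = "design_matrix")
}

#' Fit the mass-univariate general linear model
#'
#' Fits the same multiple regression independently at every grid cell by
#' ordinary least squares through the Moore-Penrose pseudoinverse:
#' `beta = (X'X)^- X' y`, residual variance `sigma2 = r'r / nu` with
#' `nu = N - rank(X)`. Cells whose responses are identically zero are
#' flagged degenerate (`sigma2 = 0`); cells outside the mask are absent.
#'
#' @param stack A [build_response_stack()] result, or an `N x n_cells`
#'   response matrix.
#' @param design A [build_design()] result (or plain matrix).
#' @param grid Required when `stack` is a plain matrix.
#' @param scale When `stack` holds several scales, which one to fit.
#' @param mask Optional logical matrix restricting the fit.
#' @return An object of class `mu_fit`: `beta` (Q x M), `sigma2` (length
#'   M), `residuals` (N x M), `nu`, `rank`, `XtX_pinv`, `X`, `mask`
#'   (logical length M), `degenerate` (logical length M), `grid`.
#' @export
fit_mass_univariate <- function(stack, design, grid = NULL, scale = NULL,
                                mask = NULL) {
  if (inherits(stack, "response_stack")) {
    grid <- stack$grid
    if (is.null(scale)) {
      if (length(stack$scales) > 1L)
        stop("stack holds several scales; pick one with `scale =`")
      scale <- stack$scales[[1]]
    }
    Y <- stack$data[[as.character(scale)]]
    if (is.null(Y)) stop(sprintf("scale %s not present in stack", scale))
  } else {
    Y <- as.matrix(stack)
    if (is.null(grid)) stop("grid must be supplied with a plain response matrix")
  }
  if (!inherits(design, "design_matrix")) design <- design_from_matrix(design)
  X <- design$X
  n <- nrow(X)
  if (nrow(Y) != n) stop("response and design have different N")
  rk <- design$rank
  nu <- n - rk
  if (nu < 1L) stop("residual degrees of freedom nu = N - rank(X) must be >= 1")
  if (rk < ncol(X))
    warning(sprintf("design is rank deficient (rank %d < %d columns); %s",
                    rk, ncol(X), "coefficients use the pseudoinverse"))

  m <- ncol(Y)
  keep <- if (is.null(mask)) rep(TRUE, m) else as.vector(mask)
  if (length(keep) != m) stop("mask does not match the grid")

  XtX_pinv <- MASS::ginv(crossprod(X))
  full <- all(keep)
  Ym <- if (full) Y else Y[, keep, drop = FALSE]
  beta_m <- XtX_pinv %*% crossprod(X, Ym)
  res_m <- Ym - X %*% beta_m
  sigma2_m <- colSums(res_m^2) / nu

  if (full) {
    beta <- beta_m; sigma2 <- sigma2_m; residuals <- res_m
    dimnames(beta) <- list(design$term_names, NULL)
  } else {
    beta <- matrix(NA_real_, ncol(X), m, dimnames = list(design$term_names, NULL))
    sigma2 <- rep(NA_real_, m)
    residuals <- matrix(NA_real_, n, m)
    beta[, keep] <- beta_m
    sigma2[keep] <- sigma2_m
    residuals[, keep] <- res_m
  }
  rm(Ym, res_m)
  degenerate <- keep & !is.na(sigma2) &
    (sigma2 <= .Machine$double.eps * colSums(Y^2) / max(nu, 1))

  structure(list(beta = beta, sigma2 = sigma2, residuals = residuals,
                 nu = nu, rank = rk, XtX_pinv = XtX_pinv, X = X,
                 term_names = design$term_names, mask = keep,
                 degenerate = degenerate, grid = grid),
            class = "mu_fit")
}

#' @export
print.mu_fit <- function(x, ...) {
  cat(sprintf("<mu_fit> %d terms, N = %d, nu = %d, %d/%d cells fitted\n",
              nrow(x$beta), nrow(x$X), x$nu, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Contrast t map
#'
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^- c)` at every fitted cell.
#' Degenerate cells (zero residual variance) and cells outside the mask
#' are returned as `NA`.
#'
#' @param fit A [fit_mass_univariate()] result.
#' @param contrast Numeric vector of length Q, or the name of a single
#'   term (elementary contrast).
#' @return An `n_rows x n_cols` matrix of t statistics.
#' @export
contrast_t_map <- function(fit, contrast) {
  q <- nrow(fit$beta)
  if (is.character(contrast)) {
    stopifnot(length(contrast) == 1L)
    i <- match(contrast, fit$term_names)
    if (is.na(i)) stop(sprintf("unknown term '%s'", contrast))
    contrast <- replace(numeric(q), i, 1)
  }
  if (length(contrast) != q) stop("contrast length must equal the number of terms")
  contrast <- as.numeric(contrast)
  cvar <- drop(t(contrast) %*% fit$XtX_pinv %*% contrast)
  # estimability: c must lie in the row space of X
  XtX <- crossprod(fit$X)
  if (max(abs(XtX %*% fit$XtX_pinv %*% contrast - contrast)) >
      1e-8 * max(1, max(abs(contrast))))
    stop("contrast is not estimable under this design")
  if (cvar <= 0) stop("contrast variance c'(X'X)^- c must be positive")
  eff <- drop(crossprod(contrast, fit$beta))
  se <- sqrt(fit$sigma2 * cvar)
  t <- eff / se
  t[fit$degenerate | !fit$mask] <- NA_real_
  matrix(t, nrow = fit$grid$n_rows, ncol = fit$grid$n_cols)
}

#' Condition-vs-rest contrasts for a one-hot design
#'
#' For K mutually exclusive condition dummies, the contrast for condition
#' k compares the mean response under condition k with the pooled mean of
#' all remaining observations: `c_k = e_k - sum_{j != k} w_j e_j` with
#' `w_j = n_j / (N - n_k)`. Because every condition coefficient estimates
#' the same mean-density field when the labels carry no spatial
#' information, the contrast has zero expectation under such a null;
#' weighting the rest by prevalence makes it the plain "is condition k
#' over-represented here relative to everyone else" comparison. With
#' equal group sizes it reduces to `e_k - mean(others)`.
#'
#' @param counts A `mu_fit` on a one-hot design (group sizes are taken
#'   from its design), the vector of per-condition observation counts,
#'   or a plain integer K (equal weights).
#' @return A K x K matrix whose rows are the contrasts.
#' @export
condition_contrasts <- function(counts) {
  if (inherits(counts, "mu_fit")) counts <- colSums(counts$X)
  if (length(counts) == 1L) counts <- rep(1, counts)
  k <- length(counts)
  if (k < 2L) stop("need at least two conditions")
  if (any(counts <= 0)) stop("every condition must have observations")
  m <- diag(k)
  for (i in seq_len(k))
    m[i, -i] <- -counts[-i] / sum(counts[-i])
  rownames(m) <- names(counts)
  m
}
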