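#' Define a regular raster grid
#'
#' A `grid_spec` ties 0-based cell indices (j, k) to planar coordinates.
#' Cells are square; the centre of cell (j, k) is at
#' `(origin_x + (j + 0.5) * cell_size, origin_y + (k + 0.5) * cell_size)`,
#' with j indexing columns (x, eastward) and k indexing rows (y, northward).
#' Rasters built on the grid are `n_rows x n_cols` matrices whose row r
#' corresponds to k = r - 1, i.e. row 1 is the southernmost row.
#'
#' @param n_cols,n_rows Number of grid columns and rows (at least 1).
#' @param cell_size Side length of a (square) cell, in planar length units.
#' @param origin_x,origin_y Coordinates of the grid's south-west corner.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(120, 120)
#' cell_centers(g)[1, ] # centre of cell (0, 0)
#' @export
grid_spec <- function(n_cols, n_rows, cell_size = 1, origin_x = 0, origin_y = 0) {
  stopifnot(is.numeric(n_cols), is.numeric(n_rows), is.numeric(cell_size))
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (n_cols < 1L || n_rows < 1L)
    stop("grid must have at least one row and one column")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be positive and finite")
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         n_cols = n_cols, n_rows = n_rows),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, cell %g, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

grid_extent <- function(grid) {
  c(xmin = grid$origin_x, xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymin = grid$origin_y, ymax = grid$origin_y + grid$n_rows * grid$cell_size)
}

grid_diagonal <- function(grid) {
  e <- grid_extent(grid)
  sqrt((e[["xmax"]] - e[["xmin"]])^2 + (e[["ymax"]] - e[["ymin"]])^2)
}

#' Cell-centre coordinates of every grid cell
#'
#' @param grid A [grid_spec()].
#' @return An `n_cells x 2` matrix of (x, y) cell centres in raster flat
#'   order (row index varies fastest, matching R's column-major matrices).
#' @export
cell_centers <- function(grid) {
  j <- rep(seq_len(grid$n_cols) - 1L, each = grid$n_rows)
  k <- rep(seq_len(grid$n_rows) - 1L, times = grid$n_cols)
  cbind(x = grid$origin_x + (j + 0.5) * grid$cell_size,
        y = grid$origin_y + (k + 0.5) * grid$cell_size)
}

#' Build an observation table
#'
#' Holds N point observations: planar locations plus a numeric matrix of
#' observed variable values (one column per variable).
#'
#' @param locations An `N x 2` numeric matrix (or two-column data frame) of
#'   planar (x, y) coordinates; all coordinates must be finite.
#' @param values An `N x P` numeric matrix of observed values; a vector is
#'   treated as a single variable.
#' @param variable_names Optional character vector of P variable names.
#' @return An object of class `observation_table` with elements
#'   `locations`, `values`, `variable_names`.
#' @export
observation_table <- function(locations, values, variable_names = NULL) {
  locations <- as.matrix(locations)
  if (ncol(locations) != 2L) stop("locations must have two columns (x, y)")
  storage.mode(locations) <- "double"
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(locations))
    stop("locations and values must have the same number of rows")
  if (nrow(locations) < 1L) stop("at least one observation is required")
  if (any(!is.finite(locations)))
    stop("all observation locations must be finite")
  if (is.null(variable_names)) {
    variable_names <- colnames(values)
    if (is.null(variable_names))
      variable_names <- paste0("v", seq_len(ncol(values)))
  }
  if (length(variable_names) != ncol(values))
    stop("variable_names must match the number of value columns")
  colnames(values) <- variable_names
  colnames(locations) <- c("x", "y")
  structure(list(locations = locations, values = values,
                 variable_names = variable_names),
            class = "observation_table")
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("<observation_table> N = %d, variables: %s\n",
              nrow(x$locations), paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

n_obs <- function(obs) nrow(obs$locations)

#' Kernel standard deviation from a 95\% iso-density diameter
#'
#' The smoothing scale s is specified as the diameter of the circle that
#' contains 95\% of the mass of an isotropic bivariate Gaussian centred at
#' its middle. Inverting the circular-mass relation
#' `P(R <= r) = 1 - exp(-r^2 / (2 sigma^2))` at 0.95 gives
#' `sigma = (s / 2) / sqrt(2 log 20)`.
#'
#' @param diameter_s Smoothing diameter, in planar length units (positive).
#' @return The kernel standard deviation, same units.
#' @examples
#' sigma_from_diameter(60) # 12.256...
#' @export
sigma_from_diameter <- function(diameter_s) {
  if (!is.numeric(diameter_s) || any(!is.finite(diameter_s)) || any(diameter_s <= 0))
    stop("diameter_s must be a positive finite number")
  (diameter_s / 2) / sqrt(2 * log(20))
}

#' Construct a smoothing kernel
#'
#' @param diameter_s 95\% iso-density diameter of the kernel.
#' @param truncation_factor Hard-truncation radius in units of sigma
#'   (default 4; the mass lost beyond 4 sigma is below 0.04\%).
#' @return An object of class `smoothing_kernel` with fields `diameter_s`,
#'   `sigma`, `truncation_radius`.
#' @export
smoothing_kernel <- function(diameter_s, truncation_factor = 4) {
  sigma <- sigma_from_diameter(diameter_s)
  if (truncation_factor < 3)
    stop("truncation_factor must be at least 3 sigma")
  structure(list(diameter_s = diameter_s, sigma = sigma,
                 truncation_radius = truncation_factor * sigma),
            class = "smoothing_kernel")
}

kernel_peak <- function(kernel, grid) {
  grid$cell_size^2 / (2 * pi * kernel$sigma^2)
}

check_kernel_resolution <- function(kernel, grid) {
  if (kernel$sigma < 0.5 * grid$cell_size) {
    min_s <- grid$cell_size * sqrt(2 * log(20))
    stop(sprintf(paste0("kernel is under-resolved on this grid: sigma = %.4g < ",
                        "cell_size / 2; smallest admissible diameter is %.4g"),
                 kernel$sigma, min_s))
  }
  invisible(TRUE)
}

#' Rasterize one observation as a Gaussian response
#'
#' Evaluates a unit-mass isotropic Gaussian density centred at `location`
#' at every cell centre, multiplied by the cell area, with a hard zero
#' beyond the kernel's truncation radius. For kernels fully interior to
#' the grid the raster sums to ~1.
#'
#' @param location Length-2 numeric (x, y).
#' @param kernel A [smoothing_kernel()].
#' @param grid A [grid_spec()].
#' @return An `n_rows x n_cols` matrix of non-negative responses.
#' @export
rasterize_observation <- function(location, kernel, grid) {
  if (length(location) != 2L || any(!is.finite(location)))
    stop("location must be a finite (x, y) pair")
  check_kernel_resolution(kernel, grid)
  v <- rasterize_points_cpp(location[[1]], location[[2]], kernel$sigma,
                            kernel$truncation_radius,
                            grid$origin_x, grid$origin_y, grid$cell_size,
                            grid$n_rows, grid$n_cols)
  matrix(v[1L, ], nrow = grid$n_rows, ncol = grid$n_cols)
}

# N x M response matrix for all observations at one scale (flat cell order)
rasterize_all <- function(obs, kernel, grid) {
  check_kernel_resolution(kernel, grid)
  rasterize_points_cpp(obs$locations[, 1L], obs$locations[, 2L],
                       kernel$sigma, kernel$truncation_radius,
                       grid$origin_x, grid$origin_y, grid$cell_size,
                       grid$n_rows, grid$n_cols)
}

#' Build a multi-scale response stack
#'
#' Rasterizes every observation at every requested smoothing scale. The
#' per-scale responses are the dependent variable of the mass-univariate
#' regression.
#'
#' @param obs An [observation_table()].
#' @param scales Strictly increasing vector of smoothing diameters.
#' @param grid A [grid_spec()].
#' @param truncation_factor Passed to [smoothing_kernel()].
#' @return An object of class `response_stack`: list with `scales`,
#'   `grid`, `kernels`, and `data` — a named list (one element per scale)
#'   of `N x n_cells` matrices in raster flat order.
#' @export
build_response_stack <- function(obs, scales, grid, truncation_factor = 4) {
  if (length(scales) < 1L) stop("scales must be non-empty")
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing")
  kernels <- lapply(scales, smoothing_kernel, truncation_factor = truncation_factor)
  data <- lapply(kernels, function(k) rasterize_all(obs, k, grid))
  names(data) <- names(kernels) <- as.character(scales)
  structure(list(scales = scales, grid = grid, kernels = kernels, data = data),
            class = "response_stack")
}

#' @export
print.response_stack <- function(x, ...) {
  cat(sprintf("<response_stack> N = %d, %d scale(s): %s; grid %d x %d\n",
              nrow(x$data[[1]]), length(x$scales),
              paste(x$scales, collapse = ", "), x$grid$n_cols, x$grid$n_rows))
  invisible(x)
}

#' Density support mask
#'
#' Marks cells where the combined smoothing density of all observations
#' reaches `factor` times the peak value of a single kernel raster. Used
#' to restrict inference to adequately sampled areas.
#'
#' @param obs An [observation_table()].
#' @param kernel A [smoothing_kernel()].
#' @param grid A [grid_spec()].
#' @param factor Multiple of the single-kernel peak required (default 10).
#' @return A logical `n_rows x n_cols` matrix.
#' @export
density_mask <- function(obs, kernel, grid, factor = 10) {
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  y <- rasterize_all(obs, kernel, grid)
  total <- colSums(y)
  matrix(total >= factor * kernel_peak(kernel, grid),
         nrow = grid$n_rows, ncol = grid$n_cols)
}
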