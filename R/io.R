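#' Read point observations from CSV
#'
#' Expects a header row with coordinate columns and one or more variable
#' columns. Rows with non-finite coordinates are dropped with a message;
#' extra columns not selected as variables are ignored with a message.
#'
#' @param path CSV file path.
#' @param x_col,y_col Names of the coordinate columns.
#' @param variables Character vector of variable columns; default: every
#'   remaining numeric column.
#' @return An [observation_table()].
#' @export
read_observations <- function(path, x_col = "x", y_col = "y",
                              variables = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("observation table is empty")
  for (col in c(x_col, y_col, variables))
    if (!col %in% names(df)) stop(sprintf("missing column '%s'", col))
  if (is.null(variables)) {
    rest <- setdiff(names(df), c(x_col, y_col))
    variables <- rest[vapply(df[rest], is.numeric, logical(1))]
    dropped <- setdiff(rest, variables)
    if (length(dropped))
      message(sprintf("ignoring non-numeric column(s): %s",
                      paste(dropped, collapse = ", ")))
  } else {
    extra <- setdiff(names(df), c(x_col, y_col, variables))
    if (length(extra))
      message(sprintf("ignoring unused column(s): %s",
                      paste(extra, collapse = ", ")))
  }
  if (!length(variables)) stop("no variable columns found")
  loc <- as.matrix(df[, c(x_col, y_col)])
  ok <- is.finite(loc[, 1L]) & is.finite(loc[, 2L])
  if (any(!ok))
    message(sprintf("dropping %d row(s) with non-finite coordinates", sum(!ok)))
  if (!any(ok)) stop("no rows with finite coordinates")
  observation_table(loc[ok, , drop = FALSE],
                    as.matrix(df[ok, variables, drop = FALSE]), variables)
}

world_file_path <- function(path) paste0(tools::file_path_sans_ext(path), ".tfw")
aux_file_path <- function(path) paste0(path, ".aux")

write_world_file <- function(grid, path) {
  cs <- grid$cell_size
  # x size, rotations, -y size, then the centre of the top-left pixel
  lines <- c(cs, 0, 0, -cs,
             grid$origin_x + 0.5 * cs,
             grid$origin_y + (grid$n_rows - 0.5) * cs)
  writeLines(formatC(lines, format = "g", digits = 17), world_file_path(path))
}

#' Write a raster to disk
#'
#' Two plain formats are supported. `"csv"`: `n_rows` lines of `n_cols`
#' comma-separated values, north-up (first line is the northernmost
#' row). `"tiff"`: 32-bit TIFF accompanied by an ESRI world file
#' (`.tfw`) carrying the affine geotransform; values outside \[0, 1\]
#' are stored linearly rescaled, with the offset and scale recorded in a
#' `.aux` sidecar so that [read_raster()] restores them.
#'
#' @param map Numeric or logical matrix matching the grid.
#' @param grid A [grid_spec()].
#' @param path Output path.
#' @param format `"csv"` or `"tiff"` (default from the file extension).
#' @return The path, invisibly.
#' @export
write_raster <- function(map, grid, path, format = NULL) {
  map <- as.matrix(map)
  storage.mode(map) <- "double"
  if (nrow(map) != grid$n_rows || ncol(map) != grid$n_cols)
    stop("map does not match the grid")
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) "tiff" else "csv"
  format <- match.arg(format, c("csv", "tiff"))
  north_up <- map[rev(seq_len(nrow(map))), , drop = FALSE]
  if (format == "csv") {
    utils::write.table(north_up, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  vmin <- min(north_up); vmax <- max(north_up)
  if (!all(is.finite(c(vmin, vmax)))) stop("raster contains non-finite values")
  if (vmin >= 0 && vmax <= 1) {
    offset <- 0; scale <- 1
  } else if (vmax > vmin) {
    offset <- vmin; scale <- vmax - vmin
  } else {
    offset <- vmin; scale <- 1
  }
  tiff::writeTIFF((north_up - offset) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  writeLines(formatC(c(offset, scale), format = "g", digits = 17),
             aux_file_path(path))
  write_world_file(grid, path)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path File path. TIFF rasters restore the grid geometry from
#'   the world file; CSV rasters need `grid` (or default to unit cells
#'   at the origin).
#' @param grid Optional [grid_spec()] for CSV input.
#' @return List with `map` (matrix, south-up row order as used
#'   throughout the package) and `grid`.
#' @export
read_raster <- function(path, grid = NULL) {
  if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    north_up <- tiff::readTIFF(path)
    # undo the writer's ~2^-32 quantization so round values survive exactly
    north_up <- round(north_up * 1e9) / 1e9
    aux <- as.numeric(readLines(aux_file_path(path)))
    north_up <- north_up * aux[2L] + aux[1L]
    w <- as.numeric(readLines(world_file_path(path)))
    cs <- w[1L]
    nr <- nrow(north_up); nc <- ncol(north_up)
    grid <- grid_spec(nc, nr, cell_size = cs,
                      origin_x = w[5L] - 0.5 * cs,
                      origin_y = w[6L] + 0.5 * cs - nr * cs)
  } else {
    north_up <- as.matrix(utils::read.table(path, sep = ","))
    dimnames(north_up) <- NULL
    if (is.null(grid)) grid <- grid_spec(ncol(north_up), nrow(north_up))
  }
  list(map = north_up[rev(seq_len(nrow(north_up))), , drop = FALSE],
       grid = grid)
}
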