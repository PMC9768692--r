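#' Assemble and validate a run configuration
#'
#' @param input Path to an observation CSV, or an [observation_table()].
#' @param scales Vector of smoothing diameters (strictly increasing).
#' @param x_col,y_col,variables Column mapping for CSV input.
#' @param grid Optional [grid_spec()]; when `NULL` the grid is derived
#'   from the data bounding box padded by one truncation radius of the
#'   largest kernel, with `cell_size` such that the smallest smoothing
#'   diameter spans at least 5 cells.
#' @param cell_size Cell size for the auto-derived grid (default
#'   `min(scales) / 5`).
#' @param design A [design_spec()], or `"one_hot"` to analyse the
#'   thresholded spatial conditions with condition-vs-rest contrasts.
#' @param contrasts Optional named list of contrast vectors; default:
#'   one elementary contrast per non-intercept term.
#' @param alpha Family-wise error rate (default 0.05).
#' @param tails `"one"` or `"two"`.
#' @param mask_factor Density-mask factor (see [density_mask()]); `NULL`
#'   disables masking.
#' @param output_dir Where to write rasters and summaries.
#' @param format Raster format, `"csv"` or `"tiff"`.
#' @param seed Recorded in the resolved config (analysis itself is
#'   deterministic).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input, scales, x_col = "x", y_col = "y",
                       variables = NULL, grid = NULL, cell_size = NULL,
                       design = "one_hot", contrasts = NULL, alpha = 0.05,
                       tails = c("one", "two"), mask_factor = NULL,
                       output_dir = "geoparmap_out", format = c("csv", "tiff"),
                       seed = 1L) {
  tails <- match.arg(tails)
  format <- match.arg(format)
  if (!length(scales) || is.unsorted(scales, strictly = TRUE))
    stop("scales must be non-empty and strictly increasing")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!is.null(mask_factor) && mask_factor <= 0) stop("mask_factor must be positive")
  one_hot <- identical(design, "one_hot")
  if (!one_hot && !inherits(design, "design_spec"))
    stop("design must be a design_spec() or \"one_hot\"")
  structure(list(input = input, scales = scales, x_col = x_col, y_col = y_col,
                 variables = variables, grid = grid, cell_size = cell_size,
                 design = design, contrasts = contrasts, alpha = alpha,
                 tails = tails, mask_factor = mask_factor,
                 output_dir = output_dir, format = format,
                 seed = as.integer(seed)),
            class = "run_config")
}

auto_grid <- function(obs, scales, cell_size = NULL) {
  if (is.null(cell_size)) cell_size <- min(scales) / 5
  pad <- smoothing_kernel(max(scales))$truncation_radius
  xr <- range(obs$locations[, 1L]); yr <- range(obs$locations[, 2L])
  ox <- xr[1L] - pad; oy <- yr[1L] - pad
  grid_spec(n_cols = ceiling((xr[2L] + pad - ox) / cell_size),
            n_rows = ceiling((yr[2L] + pad - oy) / cell_size),
            cell_size = cell_size, origin_x = ox, origin_y = oy)
}

resolved_config <- function(config, grid, n, variables) {
  list(input = if (is.character(config$input)) config$input else "<in-memory>",
       n_observations = n, variables = variables,
       scales = config$scales,
       grid = list(n_cols = grid$n_cols, n_rows = grid$n_rows,
                   cell_size = grid$cell_size,
                   origin_x = grid$origin_x, origin_y = grid$origin_y),
       design = if (identical(config$design, "one_hot")) "one_hot"
                else list(terms = config$design$terms,
                          intercept = config$design$intercept),
       alpha = config$alpha, tails = config$tails,
       mask_factor = config$mask_factor, format = config$format,
       seed = config$seed, package_version = as.character(utils::packageVersion("geoparmap")))
}

#' Run the full mapping pipeline
#'
#' Reads the observations, builds (or derives) the grid, fits the
#' mass-univariate model at every smoothing scale, thresholds every
#' contrast's t map at the voxel-level FWE-corrected critical value, and
#' writes per-scale beta / t / significance rasters plus a run summary
#' CSV (threshold, smoothness, resels, significant-cell counts), the
#' fully resolved configuration (YAML) and a log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary` (data frame), `grid`, and
#'   `maps` (per scale: t maps and significance maps per contrast).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(fmt, ...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                       sprintf(fmt, ...)), log_con)
  }
  stage <- "read observations"
  result <- tryCatch({
    obs <- if (inherits(config$input, "observation_table")) config$input
           else read_observations(config$input, config$x_col, config$y_col,
                                  config$variables)
    logf("read %d observations (%s)", n_obs(obs),
         paste(obs$variable_names, collapse = ", "))

    stage <- "grid setup"
    grid <- if (is.null(config$grid)) auto_grid(obs, config$scales, config$cell_size)
            else config$grid
    logf("grid: %d x %d cells of size %g", grid$n_cols, grid$n_rows,
         grid$cell_size)

    stage <- "design"
    one_hot <- identical(config$design, "one_hot")
    if (one_hot) {
      onehot <- one_hot_conditions(obs)
      keep <- colSums(onehot$values) > 0
      design <- design_from_matrix(onehot$values[, keep, drop = FALSE])
      contrasts <- asplit(condition_contrasts(colSums(design$X)), 1L)
      names(contrasts) <- design$term_names
      fit_obs <- onehot
    } else {
      design <- build_design(obs, config$design)
      contrasts <- config$contrasts
      if (is.null(contrasts)) {
        terms <- setdiff(design$term_names, "intercept")
        contrasts <- lapply(terms, function(tm)
          replace(numeric(length(design$term_names)), match(tm, design$term_names), 1))
        names(contrasts) <- terms
      }
      fit_obs <- obs
    }
    logf("design: %s (rank %d)", paste(design$term_names, collapse = " + "),
         design$rank)

    summary_rows <- list()
    maps <- list()
    ext <- if (config$format == "tiff") "tif" else "csv"
    for (s in config$scales) {
      stage <- sprintf("scale %g", s)
      kernel <- smoothing_kernel(s)
      mask <- if (is.null(config$mask_factor)) NULL
              else density_mask(fit_obs, kernel, grid, config$mask_factor)
      Y <- rasterize_all(fit_obs, kernel, grid)
      fit <- fit_mass_univariate(Y, design, grid, mask = mask)
      sm <- estimate_fwhm(standardize_residuals(fit), grid)
      valid <- matrix(fit$mask & !fit$degenerate, grid$n_rows, grid$n_cols)
      resels <- resel_counts(valid, sm$fwhm_x, sm$fwhm_y)
      thr <- fwe_threshold(config$alpha, fit$nu, resels, sum(valid),
                           config$tails)
      logf("scale %g: fwhm (%.2f, %.2f) cells, threshold t = %.4f",
           s, sm$fwhm_x, sm$fwhm_y, thr)
      scale_maps <- list()
      for (cname in names(contrasts)) {
        cvec <- contrasts[[cname]]
        t_map <- contrast_t_map(fit, cvec)
        sig <- threshold_map(t_map, thr, config$tails, valid, config$alpha)
        safe <- gsub("[^A-Za-z0-9_.-]", "_", cname)
        beta_map <- matrix(drop(crossprod(cvec, fit$beta)),
                           grid$n_rows, grid$n_cols)
        write_raster(beta_map, grid,
                     file.path(config$output_dir,
                               sprintf("beta_%s_s%g.%s", safe, s, ext)))
        t_out <- t_map; t_out[is.na(t_out)] <- 0
        write_raster(t_out, grid,
                     file.path(config$output_dir,
                               sprintf("t_%s_s%g.%s", safe, s, ext)))
        write_raster(sig$significant, grid,
                     file.path(config$output_dir,
                               sprintf("sig_%s_s%g.%s", safe, s, ext)))
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          scale = s, contrast = cname, threshold_t = thr, nu = fit$nu,
          fwhm_x = sm$fwhm_x, fwhm_y = sm$fwhm_y,
          resels_0 = resels[[1]], resels_1 = resels[[2]], resels_2 = resels[[3]],
          n_masked = sum(valid), n_significant = sum(sig$significant))
        scale_maps[[cname]] <- list(t = t_map, significance = sig)
      }
      maps[[as.character(s)]] <- scale_maps
    }
    stage <- "summaries"
    summary <- do.call(rbind, summary_rows)
    utils::write.csv(summary, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    yaml::write_yaml(resolved_config(config, grid, n_obs(obs),
                                     obs$variable_names),
                     file.path(config$output_dir, "config.yaml"))
    logf("done: %d contrast x scale map(s)", nrow(summary))
    list(summary = summary, grid = grid, maps = maps)
  }, error = function(e) {
    logf("ERROR in stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
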