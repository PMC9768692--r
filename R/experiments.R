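#' Per-condition significance analysis at one smoothing scale
#'
#' Rasterizes the observations at one scale, fits the one-hot condition
#' design (no intercept), estimates residual smoothness, computes the
#' voxel-level FWE-corrected one-tailed threshold, and thresholds the
#' condition-vs-rest contrast t map of every condition. Conditions with
#' no observations are dropped from the design and reported as empty
#' maps.
#'
#' @param onehot An [one_hot_conditions()] result.
#' @param grid A [grid_spec()].
#' @param diameter Smoothing diameter.
#' @param alpha Family-wise error rate (default 0.05).
#' @param tails `"one"` (default) or `"two"`.
#' @return List: `maps` (named list of [threshold_map()] results, one per
#'   condition), `threshold`, `smoothness`, `resels`, `nu`, `fit` (the
#'   fit is returned without its residual matrix: the analysis streams
#'   over observation chunks so large grids stay within memory).
#' @export
condition_significance <- function(onehot, grid, diameter, alpha = 0.05,
                                   tails = "one") {
  counts <- colSums(onehot$values)
  keep <- counts > 0
  if (sum(keep) < 2L)
    stop("fewer than two conditions have observations; no contrast is possible")
  X <- onehot$values[, keep, drop = FALSE]
  kernel <- smoothing_kernel(diameter)
  check_kernel_resolution(kernel, grid)
  fs <- stream_fit_smoothness(X, onehot, kernel, grid)
  fit <- fs$fit; sm <- fs$smoothness
  valid <- matrix(fit$mask & !fit$degenerate, grid$n_rows, grid$n_cols)
  resels <- resel_counts(valid, sm$fwhm_x, sm$fwhm_y)
  thr <- fwe_threshold(alpha, fit$nu, resels, sum(valid), tails)

  contrasts <- condition_contrasts(counts[keep])
  empty <- threshold_map(matrix(NA_real_, grid$n_rows, grid$n_cols),
                         thr, tails, mask = valid, alpha = alpha)
  maps <- vector("list", length(counts))
  names(maps) <- colnames(onehot$values)
  ki <- 0L
  for (k in seq_along(maps)) {
    if (!keep[k]) { maps[[k]] <- empty; next }
    ki <- ki + 1L
    t_map <- contrast_t_map(fit, contrasts[ki, ])
    maps[[k]] <- threshold_map(t_map, thr, tails, mask = valid, alpha = alpha)
  }
  list(maps = maps, threshold = thr, smoothness = sm, resels = resels,
       nu = fit$nu, fit = fit)
}

# conditions in which a variable equals 1, by condition label convention
conditions_with_variable <- function(condition_names, variable) {
  patterns <- sub("^cond_", "", condition_names)
  if (variable == "Z") return(condition_names[patterns == "1"])
  pos <- match(variable, c("Z1", "Z2"))
  if (is.na(pos)) stop(sprintf("unknown variable '%s'", variable))
  condition_names[substr(patterns, pos, pos) == "1"]
}

#' Multi-scale recovery of model variables
#'
#' Runs [condition_significance()] at every smoothing scale, selects the
#' scale maximizing the coverage score (ties to the smallest scale), and
#' returns per-variable significance maps at the selected scale: the
#' union of the condition maps of all conditions in which the variable
#' equals 1.
#'
#' @param obs An [observation_table()] with 1 or 2 binary variables.
#' @param grid A [grid_spec()].
#' @param scales Vector of smoothing diameters.
#' @param alpha Family-wise error rate.
#' @return List: `selected_scale`, `coverage` (named by scale),
#'   `variable_maps` (named list of logical matrices),
#'   `condition_maps` (at the selected scale), `threshold`.
#' @export
recover_variables <- function(obs, grid, scales, alpha = 0.05) {
  onehot <- one_hot_conditions(obs)
  per_scale <- lapply(scales, function(s) {
    res <- condition_significance(onehot, grid, s, alpha = alpha, tails = "one")
    res$fit <- NULL # keep only maps and summaries across scales
    gc(verbose = FALSE)
    res
  })
  coverage <- vapply(per_scale, function(r) coverage_score(r$maps), numeric(1))
  names(coverage) <- as.character(scales)
  s_star <- select_scale(coverage, scales)
  sel <- per_scale[[match(s_star, scales)]]
  vars <- obs$variable_names
  variable_maps <- lapply(vars, function(v) {
    use <- conditions_with_variable(names(sel$maps), v)
    Reduce(`|`, lapply(sel$maps[use], function(m) m$significant))
  })
  names(variable_maps) <- vars
  list(selected_scale = s_star, coverage = coverage,
       variable_maps = variable_maps, condition_maps = sel$maps,
       threshold = sel$threshold)
}

#' Default noise grid of the synthetic experiments
#'
#' @return Gamma levels 0.00 to 0.35 in steps of 0.01 (36 levels).
#' @export
noise_gamma_grid <- function() seq(0, 0.35, by = 0.01)

#' Enumerate the jobs of a noise experiment
#'
#' One row per dataset to be generated: every combination of model,
#' sampling level, noise level and repetition.
#'
#' @param models Character vector of model kinds.
#' @param n_values Sampling levels.
#' @param gammas Noise levels (default [noise_gamma_grid()]).
#' @param n_reps Repetitions per (model, N, gamma) triplet (default 10).
#' @return A data frame with columns `model`, `n`, `parameter`, `rep`.
#' @export
enumerate_noise_grid <- function(models, n_values,
                                 gammas = noise_gamma_grid(), n_reps = 10) {
  jobs <- expand.grid(rep = seq_len(n_reps), parameter = gammas, n = n_values,
                      model = models, stringsAsFactors = FALSE)
  jobs[, c("model", "n", "parameter", "rep")]
}

#' Enumerate the jobs of an interaction experiment
#'
#' @param c3_values Interaction strengths (default 0.25 to 0.5 by 0.05).
#' @param n Sampling level (default 15000).
#' @param n_reps Repetitions per level (default 10).
#' @return A data frame with columns `model`, `n`, `parameter`, `rep`.
#' @export
enumerate_interaction_grid <- function(c3_values = seq(0.25, 0.5, by = 0.05),
                                       n = 15000, n_reps = 10) {
  jobs <- expand.grid(rep = seq_len(n_reps), parameter = c3_values,
                      n = n, model = "interaction", stringsAsFactors = FALSE)
  jobs[, c("model", "n", "parameter", "rep")]
}

job_seeds <- function(master_seed, n_jobs) {
  set.seed(master_seed)
  sample.int(2147483646L, n_jobs)
}

score_variable_maps <- function(variable_maps, layout, parameter) {
  do.call(rbind, lapply(names(variable_maps), function(v) {
    target <- target_map(layout, v, parameter)
    cbind(variable = v,
          segmentation_scores(variable_maps[[v]], target, layout$grid))
  }))
}

aggregate_scores <- function(per_dataset) {
  all <- do.call(rbind, per_dataset)
  metrics <- c("jaccard", "dice", "mcc", "symmetric_uncertainty", "mhd_fraction")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(all[, c("model", "n", "parameter", "variable")],
               metric = m, value = all[[m]])
  }))
  agg <- stats::aggregate(value ~ model + n + parameter + variable + metric,
                          data = long,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v, na.rm = TRUE),
                                              n_reps = sum(!is.na(v))),
                          na.action = stats::na.pass)
  out <- data.frame(agg[, c("model", "n", "parameter", "variable", "metric")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n_reps = agg$value[, "n_reps"])
  out[order(out$model, out$n, out$parameter, out$variable, out$metric), ]
}

#' Run a replicated noise experiment
#'
#' For every (model, N, gamma, repetition) job: sample a dataset, run the
#' multi-scale one-hot analysis with coverage-based scale selection
#' ([recover_variables()]), and score each variable's significance map
#' against its ground-truth target. Scores are aggregated to mean and SD
#' over the repetitions of each triplet. A failing repetition is logged
#' and skipped; `n_reps` in the output records completed repetitions.
#'
#' @param models Character vector of model kinds.
#' @param n_values Sampling levels.
#' @param gammas Noise levels.
#' @param n_reps Repetitions per triplet.
#' @param scales Smoothing diameters searched (default the standard
#'   10-to-60 grid).
#' @param alpha Family-wise error rate (default 0.05, one-tailed).
#' @param seed Master seed; every dataset seed derives from it.
#' @param verbose Print one line per dataset?
#' @return A long-format data frame (class `experiment_result`): `model`,
#'   `n`, `parameter`, `variable`, `metric`, `mean`, `sd`, `n_reps`.
#' @export
run_noise_experiment <- function(models, n_values, gammas = noise_gamma_grid(),
                                 n_reps = 10, scales = seq(10, 60, by = 5),
                                 alpha = 0.05, seed = 1, verbose = FALSE) {
  jobs <- enumerate_noise_grid(models, n_values, gammas, n_reps)
  seeds <- job_seeds(seed, nrow(jobs))
  layouts <- sapply(unique(jobs$model), layout_for_model, simplify = FALSE)
  per_dataset <- vector("list", nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    job <- jobs[i, ]
    layout <- layouts[[job$model]]
    res <- tryCatch({
      obs <- sample_dataset(job$model, job$n, job$parameter, seeds[i],
                            layout = layout)
      rec <- recover_variables(obs, layout$grid, scales, alpha = alpha)
      cbind(job[, c("model", "n", "parameter")],
            score_variable_maps(rec$variable_maps, layout, job$parameter),
            row.names = NULL)
    }, error = function(e) {
      message(sprintf("job %d (%s, n=%d, gamma=%.2f, rep %d) failed: %s",
                      i, job$model, job$n, job$parameter, job$rep,
                      conditionMessage(e)))
      NULL
    })
    if (verbose)
      message(sprintf("[%d/%d] %s n=%d gamma=%.2f rep=%d done",
                      i, nrow(jobs), job$model, job$n, job$parameter, job$rep))
    per_dataset[[i]] <- res
  }
  out <- aggregate_scores(per_dataset[!vapply(per_dataset, is.null, logical(1))])
  class(out) <- c("experiment_result", class(out))
  out
}

#' Run a replicated interaction experiment
#'
#' For every (c3, repetition) job: sample the interaction model, build
#' the augmented design (intercept, Z1, Z2, Z1*Z2), fit at a single
#' smoothing scale, threshold each term's one-tailed t map at the
#' voxel-level FWE rate, and score the maps for Z1, Z2 and Z1*Z2 against
#' their targets.
#'
#' @param c3_values Interaction strengths.
#' @param n Sampling level (default 15000).
#' @param n_reps Repetitions per level.
#' @param scale Single smoothing diameter (default 60).
#' @param alpha Family-wise error rate.
#' @param seed Master seed.
#' @param verbose Print one line per dataset?
#' @return A long-format `experiment_result` data frame as in
#'   [run_noise_experiment()].
#' @export
run_interaction_experiment <- function(c3_values = seq(0.25, 0.5, by = 0.05),
                                       n = 15000, n_reps = 10, scale = 60,
                                       alpha = 0.05, seed = 1,
                                       verbose = FALSE) {
  jobs <- enumerate_interaction_grid(c3_values, n, n_reps)
  seeds <- job_seeds(seed, nrow(jobs))
  layout <- layout_for_model("interaction")
  spec <- design_spec(c("Z1", "Z2", "Z1*Z2"), intercept = TRUE)
  per_dataset <- vector("list", nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    job <- jobs[i, ]
    res <- tryCatch({
      obs <- sample_dataset("interaction", job$n, job$parameter, seeds[i],
                            layout = layout)
      maps <- interaction_term_maps(obs, layout$grid, spec, scale, alpha)
      cbind(job[, c("model", "n", "parameter")],
            score_variable_maps(maps, layout, job$parameter),
            row.names = NULL)
    }, error = function(e) {
      message(sprintf("job %d (c3=%.2f, rep %d) failed: %s",
                      i, job$parameter, job$rep, conditionMessage(e)))
      NULL
    })
    if (verbose)
      message(sprintf("[%d/%d] c3=%.2f rep=%d done",
                      i, nrow(jobs), job$parameter, job$rep))
    per_dataset[[i]] <- res
  }
  out <- aggregate_scores(per_dataset[!vapply(per_dataset, is.null, logical(1))])
  class(out) <- c("experiment_result", class(out))
  out
}

# one-tailed FWE-thresholded maps for each non-intercept term of a design
interaction_term_maps <- function(obs, grid, spec, scale, alpha) {
  design <- build_design(obs, spec)
  kernel <- smoothing_kernel(scale)
  check_kernel_resolution(kernel, grid)
  fs <- stream_fit_smoothness(design$X, obs, kernel, grid)
  fit <- fs$fit; sm <- fs$smoothness
  valid <- matrix(fit$mask & !fit$degenerate, grid$n_rows, grid$n_cols)
  resels <- resel_counts(valid, sm$fwhm_x, sm$fwhm_y)
  thr <- fwe_threshold(alpha, fit$nu, resels, sum(valid), "one")
  terms <- setdiff(fit$term_names, "intercept")
  maps <- lapply(terms, function(tm)
    threshold_map(contrast_t_map(fit, tm), thr, "one", valid, alpha)$significant)
  names(maps) <- terms
  maps
}

#' Empirical FWE rate under a pure-noise model
#'
#' Simulates datasets with no spatial structure — locations uniform on
#' the grid, a single binary variable assigned by an independent fair
#' coin — analyses each with the one-hot condition design at one
#' smoothing scale, and reports the fraction of runs in which the
#' positive condition's FWE-thresholded map contains any significant
#' cell. Under voxel-level control at `alpha` this fraction should not
#' exceed `alpha` (random-field-theory thresholds on smooth fields are,
#' if anything, conservative).
#'
#' @param n_sims Number of simulated null datasets.
#' @param n Observations per dataset (default 600).
#' @param grid Grid (default 120 x 120, unit cells).
#' @param diameter Smoothing diameter (default 40).
#' @param alpha Family-wise error rate (default 0.05, one-tailed).
#' @param seed Master seed.
#' @return List: `rate`, `n_sims`, `any_sig` (logical vector).
#' @export
simulate_null_fwe <- function(n_sims, n = 600, grid = grid_spec(120, 120),
                              diameter = 40, alpha = 0.05, seed = 1) {
  seeds <- job_seeds(seed, n_sims)
  e <- grid_extent(grid)
  any_sig <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(seeds[i])
    pts <- cbind(stats::runif(n, e[["xmin"]], e[["xmax"]]),
                 stats::runif(n, e[["ymin"]], e[["ymax"]]))
    z <- stats::rbinom(n, 1L, 0.5)
    obs <- observation_table(pts, z, "Z")
    res <- condition_significance(one_hot_conditions(obs), grid, diameter,
                                  alpha = alpha, tails = "one")
    any_sig[i] <- any(res$maps[["cond_1"]]$significant)
  }
  list(rate = mean(any_sig), n_sims = n_sims, any_sig = any_sig)
}
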