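#' Koch snowflake / anti-snowflake polygon
#'
#' Standard Koch construction starting from an equilateral triangle of
#' the given circumradius: at each iteration every edge is replaced by
#' four edges, erecting the middle-third equilateral triangle outward
#' (snowflake) or inward (anti-snowflake). The fractal boundary carries
#' detail at every spatial scale, which is what makes these shapes useful
#' as ground-truth regions for multi-scale recovery experiments.
#'
#' @param center Length-2 numeric (x, y).
#' @param circumradius Circumradius of the initial triangle (> 0).
#' @param order Iteration depth (0 to 8).
#' @param anti Erect replacement triangles inward instead of outward?
#' @return Object of class `snowflake_shape` with fields `center`,
#'   `circumradius`, `order`, `anti` and `polygon` — a closed
#'   counter-clockwise vertex matrix (first vertex repeated last;
#'   `3 * 4^order` distinct vertices).
#' @examples
#' sf <- koch_polygon(c(0, 0), 10, order = 4)
#' polygon_area(sf) / polygon_area(koch_polygon(c(0, 0), 10, 0)) # -> ~8/5
#' @export
koch_polygon <- function(center, circumradius, order, anti = FALSE) {
  if (order < 0 || order != round(order)) stop("order must be a non-negative integer")
  if (order > 8) stop("order > 8 refused: vertex count 3*4^order explodes")
  if (circumradius <= 0) stop("circumradius must be positive")
  ang <- pi / 2 + c(0, 1, 2) * 2 * pi / 3 # counter-clockwise, apex up
  p <- cbind(center[[1]] + circumradius * cos(ang),
             center[[2]] + circumradius * sin(ang))
  dir <- if (anti) -1 else 1
  for (it in seq_len(order)) {
    nxt <- p[c(seq_len(nrow(p))[-1L], 1L), , drop = FALSE]
    d <- nxt - p
    a <- p + d / 3
    b <- p + 2 * d / 3
    # outward normal of a CCW edge points right of the edge direction
    apex <- (a + b) / 2 + dir * sqrt(3) / 6 * cbind(d[, 2L], -d[, 1L])
    n <- nrow(p)
    out <- matrix(0, 4L * n, 2L)
    out[seq(1L, by = 4L, length.out = n), ] <- p
    out[seq(2L, by = 4L, length.out = n), ] <- a
    out[seq(3L, by = 4L, length.out = n), ] <- apex
    out[seq(4L, by = 4L, length.out = n), ] <- b
    p <- out
  }
  structure(list(center = c(center[[1]], center[[2]]),
                 circumradius = circumradius, order = as.integer(order),
                 anti = isTRUE(anti),
                 polygon = rbind(p, p[1L, , drop = FALSE])),
            class = "snowflake_shape")
}

#' Signed polygon area (shoelace formula)
#'
#' @param shape A [koch_polygon()] result or a (closed or open) vertex
#'   matrix. Counter-clockwise polygons have positive area.
#' @return The enclosed area.
#' @export
polygon_area <- function(shape) {
  p <- if (inherits(shape, "snowflake_shape")) shape$polygon else as.matrix(shape)
  if (any(p[1L, ] != p[nrow(p), ])) p <- rbind(p, p[1L, , drop = FALSE])
  i <- seq_len(nrow(p) - 1L)
  sum(p[i, 1L] * p[i + 1L, 2L] - p[i + 1L, 1L] * p[i, 2L]) / 2
}

# closed-form area ratio of the order-k Koch snowflake to its base triangle
koch_area_ratio <- function(order, anti = FALSE) {
  s <- if (order == 0) 0 else sum((4 / 9)^(0:(order - 1))) / 3
  if (anti) 1 - s else 1 + s
}

points_in_shape <- function(shape, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  mgcv::in.out(shape$polygon, pts)
}

#' Region layout of a synthetic model
#'
#' Deterministic arrangements of fractal signal regions:
#' \describe{
#'   \item{snowflake / anti_snowflake}{one centred order-4 shape of
#'     circumradius 45 on a 120 x 120 grid.}
#'   \item{snowflake_field}{a 3 x 3 array of order-3 snowflakes of
#'     circumradius 14 on a 120 x 120 grid.}
#'   \item{bivariate_snowflake / bivariate_anti}{three shapes of
#'     circumradius 28 left to right on a 240 x 120 grid: R1 (Z1 only),
#'     R3 (joint), R2 (Z2 only).}
#'   \item{interaction}{the bivariate_snowflake arrangement; R3 hosts
#'     the interaction effect.}
#' }
#'
#' @param model_kind One of the kinds above.
#' @param grid Optional [grid_spec()]; defaults to the model's standard
#'   grid (cell size 1).
#' @return Object of class `region_layout`: `grid`, `model_kind`,
#'   `regions` (named list of shapes), `bivariate` flag.
#' @export
layout_for_model <- function(model_kind, grid = NULL) {
  kinds <- c("snowflake", "anti_snowflake", "snowflake_field",
             "bivariate_snowflake", "bivariate_anti", "interaction")
  if (!model_kind %in% kinds)
    stop(sprintf("unknown model_kind '%s'", model_kind))
  bivariate <- model_kind %in% c("bivariate_snowflake", "bivariate_anti", "interaction")
  if (is.null(grid))
    grid <- if (bivariate) grid_spec(240, 120) else grid_spec(120, 120)
  e <- grid_extent(grid)
  w <- e[["xmax"]] - e[["xmin"]]; h <- e[["ymax"]] - e[["ymin"]]
  cx <- (e[["xmin"]] + e[["xmax"]]) / 2; cy <- (e[["ymin"]] + e[["ymax"]]) / 2
  if (model_kind %in% c("snowflake", "anti_snowflake")) {
    r <- 0.375 * min(w, h) # 45 cells on the default grid
    regions <- list(R1 = koch_polygon(c(cx, cy), r, 4,
                                      anti = model_kind == "anti_snowflake"))
  } else if (model_kind == "snowflake_field") {
    r <- min(w, h) / 120 * 14
    centers <- expand.grid(x = e[["xmin"]] + w * c(1, 3, 5) / 6,
                           y = e[["ymin"]] + h * c(1, 3, 5) / 6)
    regions <- lapply(seq_len(nrow(centers)), function(i)
      koch_polygon(as.numeric(centers[i, ]), r, 3))
    names(regions) <- paste0("R", seq_along(regions))
  } else {
    r <- 28 / 120 * h
    anti <- model_kind == "bivariate_anti"
    regions <- list(
      R1 = koch_polygon(c(e[["xmin"]] + w / 6, cy), r, 4, anti = anti),
      R3 = koch_polygon(c(cx, cy), r, 4, anti = anti),
      R2 = koch_polygon(c(e[["xmin"]] + 5 * w / 6, cy), r, 4, anti = anti)
    )
  }
  structure(list(grid = grid, model_kind = model_kind, regions = regions,
                 bivariate = bivariate),
            class = "region_layout")
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf("<region_layout> %s: %d region(s) on %d x %d grid\n",
              x$model_kind, length(x$regions), x$grid$n_cols, x$grid$n_rows))
  invisible(x)
}

# region membership for a matrix of points: 0 = background, otherwise the
# index into layout$regions (regions are disjoint)
region_index <- function(layout, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  idx <- integer(nrow(pts))
  for (i in seq_along(layout$regions)) {
    inside <- points_in_shape(layout$regions[[i]], pts)
    idx[inside] <- i
  }
  idx
}

#' Interaction outcome distribution in region R3
#'
#' Categorical distribution over joint outcomes
#' ((0,0), (1,0), (0,1), (1,1)) inside the interaction region:
#' `p00 = 0.025`, `p10 = p01 = 0.25 - 0.25 c3`, `p11 = 0.475 + 0.5 c3`.
#' At `c3 = 0` the distribution factorises (the product of its marginals,
#' 0.725^2, equals p11 up to rounding), and increasing c3 moves
#' probability from the discordant outcomes into (1,1), creating a pure
#' interaction effect of adjustable size.
#'
#' @param c3 Interaction strength in \[0, 0.5\].
#' @return Named numeric vector `(p00, p10, p01, p11)` summing to 1.
#' @examples
#' interaction_distribution(0.5) # p11 = 0.725, p10 = 0.125
#' @export
interaction_distribution <- function(c3) {
  if (!is.numeric(c3) || length(c3) != 1L || !is.finite(c3) || c3 < 0 || c3 > 0.5)
    stop("c3 must be a number in [0, 0.5]")
  c(p00 = 0.025, p10 = 0.25 - 0.25 * c3, p01 = 0.25 - 0.25 * c3,
    p11 = 0.475 + 0.5 * c3)
}

# outcome probability matrix for points: univariate -> cols (p0, p1);
# bivariate/interaction -> cols (p00, p10, p01, p11)
outcome_probs <- function(layout, pts, parameter) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  idx <- region_index(layout, pts)
  n <- nrow(pts)
  if (layout$model_kind == "interaction") {
    c3 <- parameter
    probs <- matrix(0, n, 4L, dimnames = list(NULL, c("p00", "p10", "p01", "p11")))
    rn <- names(layout$regions)[pmax(idx, 1L)]
    rn[idx == 0L] <- "bg"
    probs[rn == "bg", "p00"] <- 1
    probs[rn == "R1", "p10"] <- 1
    probs[rn == "R2", "p01"] <- 1
    probs[rn == "R3", ] <- matrix(interaction_distribution(c3),
                                  sum(rn == "R3"), 4L, byrow = TRUE)
    return(probs)
  }
  gamma <- parameter
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 0.5)
    stop("gamma must be in [0, 0.5) (targets are undefined at gamma >= 0.5)")
  if (!layout$bivariate) {
    p1 <- ifelse(idx > 0L, 1 - gamma, gamma)
    return(cbind(p0 = 1 - p1, p1 = p1))
  }
  rn <- names(layout$regions)[pmax(idx, 1L)]
  rn[idx == 0L] <- "bg"
  q1 <- ifelse(rn %in% c("R1", "R3"), 1 - gamma, gamma) # P(Z1 = 1)
  q2 <- ifelse(rn %in% c("R2", "R3"), 1 - gamma, gamma) # P(Z2 = 1)
  cbind(p00 = (1 - q1) * (1 - q2), p10 = q1 * (1 - q2),
        p01 = (1 - q1) * q2, p11 = q1 * q2)
}

#' Outcome distribution at a point
#'
#' Evaluates the generative model's categorical outcome distribution at a
#' single location. Univariate models return probabilities over \{0, 1\}
#' (success probability `1 - gamma` inside the shape, `gamma` outside);
#' bivariate noise models draw Z1 and Z2 independently with success
#' probability `1 - gamma` inside their respective regions (R1 or R3 for
#' Z1; R2 or R3 for Z2) and `gamma` elsewhere; the interaction model uses
#' [interaction_distribution()] inside R3 and the noise-free bivariate
#' rule in R1 and R2.
#'
#' @param layout A [layout_for_model()] result.
#' @param point Length-2 numeric location.
#' @param parameter Noise level gamma (in \[0, 0.5)) or interaction
#'   strength c3, depending on the model.
#' @return Named probability vector over the model's outcomes.
#' @export
outcome_distribution <- function(layout, point, parameter) {
  drop(outcome_probs(layout, matrix(point, ncol = 2L), parameter))
}

#' Sample a synthetic dataset
#'
#' Draws N locations uniformly over the grid extent (continuous
#' coordinates) and, at each location, an outcome from the model's local
#' distribution.
#'
#' @param model_kind See [layout_for_model()].
#' @param n Number of observations.
#' @param parameter Gamma (noise models) or c3 (interaction model).
#' @param seed Integer seed; the draw is fully reproducible.
#' @param layout Optional precomputed layout (avoids rebuilding shapes).
#' @return An [observation_table()] with variable `Z` (univariate) or
#'   `Z1`, `Z2` (bivariate / interaction).
#' @export
sample_dataset <- function(model_kind, n, parameter, seed, layout = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (is.null(layout)) layout <- layout_for_model(model_kind)
  e <- grid_extent(layout$grid)
  set.seed(seed)
  pts <- cbind(stats::runif(n, e[["xmin"]], e[["xmax"]]),
               stats::runif(n, e[["ymin"]], e[["ymax"]]))
  probs <- outcome_probs(layout, pts, parameter)
  u <- stats::runif(n)
  if (!layout$bivariate) {
    z <- as.numeric(u < probs[, "p1"])
    return(observation_table(pts, z, "Z"))
  }
  c1 <- probs[, 1L]; c2 <- c1 + probs[, 2L]; c3 <- c2 + probs[, 3L]
  cat_idx <- 1L + (u > c1) + (u > c2) + (u > c3)
  z1 <- as.numeric(cat_idx %in% c(2L, 4L))
  z2 <- as.numeric(cat_idx %in% c(3L, 4L))
  observation_table(pts, cbind(Z1 = z1, Z2 = z2))
}

#' Ground-truth target map for a model term
#'
#' A cell belongs to the target iff the probability of the term at the
#' cell centre exceeds 0.5: the marginal success probability for a
#' variable (`"Z"`, `"Z1"`, `"Z2"`), or the probability of the joint
#' outcome (1,1) for the interaction term (`"Z1*Z2"`).
#'
#' @param layout A [layout_for_model()] result (or a model kind string).
#' @param term Variable or interaction term name.
#' @param parameter Gamma or c3.
#' @return A logical `n_rows x n_cols` matrix.
#' @export
target_map <- function(layout, term, parameter) {
  if (is.character(layout)) layout <- layout_for_model(layout)
  probs <- outcome_probs(layout, cell_centers(layout$grid), parameter)
  p <- switch(term,
    Z = probs[, "p1"],
    Z1 = probs[, "p10"] + probs[, "p11"],
    Z2 = probs[, "p01"] + probs[, "p11"],
    `Z1*Z2` = probs[, "p11"],
    stop(sprintf("unknown term '%s' (expected Z, Z1, Z2 or Z1*Z2)", term))
  )
  matrix(p > 0.5, layout$grid$n_rows, layout$grid$n_cols)
}
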