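test_that("Koch polygons have the right vertex counts and areas", {
  tri <- koch_polygon(c(0, 0), 10, 0)
  expect_equal(nrow(tri$polygon) - 1L, 3L)
  a0 <- polygon_area(tri)
  expect_equal(a0, 3 * sqrt(3) / 4 * 10^2, tolerance = 1e-12) # equilateral triangle
  for (order in 0:6) {
    sf <- koch_polygon(c(3, -2), 7, order)
    expect_equal(nrow(sf$polygon) - 1L, 3L * 4L^order)
    expect_equal(polygon_area(sf) / polygon_area(koch_polygon(c(3, -2), 7, 0)),
                 geoparmap:::koch_area_ratio(order), tolerance = 1e-9)
  }
  # partial series converges to the 8/5 limit
  expect_equal(geoparmap:::koch_area_ratio(6), 8 / 5, tolerance = 0.01)
  # anti-snowflake < triangle < snowflake at equal order
  anti <- koch_polygon(c(0, 0), 10, 3, anti = TRUE)
  snow <- koch_polygon(c(0, 0), 10, 3)
  expect_lt(polygon_area(anti), a0)
  expect_gt(polygon_area(snow), a0)
  expect_equal(polygon_area(anti) / a0, geoparmap:::koch_area_ratio(3, anti = TRUE),
               tolerance = 1e-9)
  expect_error(koch_polygon(c(0, 0), 10, 9), "refused")
  expect_error(koch_polygon(c(0, 0), -1, 2), "positive")
})

test_that("model layouts are deterministic, centred and disjoint", {
  uni <- layout_for_model("snowflake")
  expect_equal(uni$grid$n_cols, 120L)
  p <- uni$regions$R1$polygon
  centroid <- colMeans(p[-nrow(p), ])
  expect_equal(unname(centroid), c(60, 60), tolerance = 1e-8)

  field <- layout_for_model("snowflake_field")
  expect_length(field$regions, 9L)

  biv <- layout_for_model("bivariate_snowflake")
  expect_equal(biv$grid$n_cols, 240L)
  expect_identical(names(biv$regions), c("R1", "R3", "R2"))
  # pairwise disjoint: no vertex of one shape inside another
  for (i in 1:2) for (j in (i + 1):3) {
    vi <- biv$regions[[i]]$polygon
    expect_false(any(geoparmap:::points_in_shape(biv$regions[[j]], vi)))
  }
  # the interaction model reuses the bivariate snowflake arrangement
  int <- layout_for_model("interaction")
  expect_equal(lapply(int$regions, function(r) r$polygon),
               lapply(biv$regions, function(r) r$polygon))
  expect_error(layout_for_model("hexagon"), "unknown model_kind")
})

test_that("noise-model outcome distributions follow the region rule", {
  uni <- layout_for_model("snowflake")
  inside <- uni$regions$R1$center
  outside <- c(2, 2)
  expect_equal(unname(outcome_distribution(uni, inside, 0)), c(0, 1))
  expect_equal(unname(outcome_distribution(uni, outside, 0.35)[["p1"]]), 0.35)
  expect_equal(sum(outcome_distribution(uni, inside, 0.2)), 1)

  biv <- layout_for_model("bivariate_snowflake")
  in_r3 <- biv$regions$R3$center
  d <- outcome_distribution(biv, in_r3, 0)
  expect_equal(unname(d[["p11"]]), 1)
  d2 <- outcome_distribution(biv, biv$regions$R1$center, 0.1)
  # Z1, Z2 independent: P(1,0) = 0.9 * 0.9 inside R1
  expect_equal(unname(d2[["p10"]]), 0.81)
  expect_equal(sum(d2), 1, tolerance = 1e-12)
  expect_error(outcome_distribution(biv, in_r3, 0.5), "gamma")
})

test_that("the interaction distribution reproduces its printed probabilities", {
  d50 <- interaction_distribution(0.5)
  expect_equal(unname(d50), c(0.025, 0.125, 0.125, 0.725))
  expect_equal(interaction_distribution(0.25)[["p11"]], 0.6)
  d0 <- interaction_distribution(0)
  # independence product of the marginals at c3 = 0
  p1 <- d0[["p10"]] + d0[["p11"]]
  p2 <- d0[["p01"]] + d0[["p11"]]
  expect_equal(p1 * p2, 0.725^2)
  expect_equal(floor(p1 * p2 * 1000) / 1000, 0.525)
  expect_equal(sum(interaction_distribution(0.37)), 1)
  expect_error(interaction_distribution(0.6), "c3")
  expect_error(interaction_distribution(-0.1), "c3")
})

test_that("sampled datasets are reproducible and match their distributions", {
  a <- sample_dataset("snowflake", 200, 0.1, seed = 5)
  b <- sample_dataset("snowflake", 200, 0.1, seed = 5)
  expect_identical(a, b)
  d <- sample_dataset("interaction", 15000, 0.3, seed = 6)
  expect_equal(nrow(d$values), 15000L)
  expect_identical(d$variable_names, c("Z1", "Z2"))

  # Monte-Carlo check of the R3 outcome frequencies at c3 = 0.5
  layout <- layout_for_model("interaction")
  big <- sample_dataset("interaction", 200000, 0.5, seed = 7, layout = layout)
  in_r3 <- geoparmap:::points_in_shape(layout$regions$R3, big$locations)
  z <- big$values[in_r3, ]
  expect_lt(abs(mean(z[, 1] == 1 & z[, 2] == 1) - 0.725), 0.01)
  expect_lt(abs(mean(z[, 1] == 1 & z[, 2] == 0) - 0.125), 0.01)
})

test_that("empirical outcome frequencies pass a goodness-of-fit test region by region", {
  layout <- layout_for_model("bivariate_snowflake")
  gamma <- 0.2
  probs_for <- function(region_names) {
    q1 <- if (any(region_names %in% c("R1", "R3"))) 1 - gamma else gamma
    q2 <- if (any(region_names %in% c("R2", "R3"))) 1 - gamma else gamma
    c((1 - q1) * (1 - q2), q1 * (1 - q2), (1 - q1) * q2, q1 * q2)
  }
  p_values <- c()
  for (seed in 1:5) {
    obs <- sample_dataset("bivariate_snowflake", 100000, gamma, seed = seed,
                          layout = layout)
    idx <- geoparmap:::region_index(layout, obs$locations)
    for (region in c(0L, 1L, 2L, 3L)) {
      sel <- idx == region
      z <- obs$values[sel, , drop = FALSE]
      counts <- c(sum(z[, 1] == 0 & z[, 2] == 0), sum(z[, 1] == 1 & z[, 2] == 0),
                  sum(z[, 1] == 0 & z[, 2] == 1), sum(z[, 1] == 1 & z[, 2] == 1))
      expected <- probs_for(if (region == 0L) "bg" else names(layout$regions)[region])
      p_values <- c(p_values, chisq.test(counts, p = expected)$p.value)
    }
  }
  # under the true model at most one of the 20 tests should reject at 0.01
  expect_lte(sum(p_values < 0.01), 1L)
})

test_that("target maps threshold the model probabilities at one half", {
  uni <- layout_for_model("snowflake")
  tgt <- target_map(uni, "Z", 0.3)
  inside <- geoparmap:::region_index(uni, cell_centers(uni$grid)) > 0
  expect_equal(as.vector(tgt), inside)

  biv <- layout_for_model("bivariate_snowflake")
  idx <- geoparmap:::region_index(biv, cell_centers(biv$grid))
  rn <- c("bg", names(biv$regions))[idx + 1L]
  expect_equal(as.vector(target_map(biv, "Z1", 0.1)), rn %in% c("R1", "R3"))
  expect_equal(as.vector(target_map(biv, "Z2", 0.1)), rn %in% c("R2", "R3"))

  int <- layout_for_model("interaction")
  idx_i <- geoparmap:::region_index(int, cell_centers(int$grid))
  rn_i <- c("bg", names(int$regions))[idx_i + 1L]
  expect_equal(as.vector(target_map(int, "Z1*Z2", 0.25)), rn_i == "R3")
  expect_equal(as.vector(target_map(int, "Z1", 0.25)), rn_i %in% c("R1", "R3"))
  expect_error(target_map(int, "Z9", 0.25), "unknown term")
})
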