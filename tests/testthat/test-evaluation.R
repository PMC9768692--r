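make_map <- function(cells, nr = 10, nc = 10) {
  m <- matrix(FALSE, nr, nc)
  m[cells] <- TRUE
  m
}

test_that("segmentation scores reproduce hand-computed cases", {
  tgt <- make_map(c(5, 6, 15, 16))
  self <- segmentation_scores(tgt, tgt)
  expect_equal(self$jaccard, 1)
  expect_equal(self$dice, 1)
  expect_equal(self$mcc, 1)
  expect_equal(self$symmetric_uncertainty, 1)
  expect_equal(self$mhd_fraction, 0)

  # A occupies 4 cells, B covers 2 of them plus 2 others
  a <- make_map(c(5, 6, 15, 16))
  b <- make_map(c(5, 6, 25, 26))
  s <- segmentation_scores(a, b)
  expect_equal(s$jaccard, 1 / 3)
  expect_equal(s$dice, 1 / 2)

  # single-cell sets: MHD is the point distance over the grid diagonal
  g <- grid_spec(100, 100)
  a1 <- matrix(FALSE, 100, 100); a1[1, 1] <- TRUE
  b1 <- matrix(FALSE, 100, 100); b1[5, 4] <- TRUE # offset (3, 4) -> distance 5
  s1 <- segmentation_scores(a1, b1, g)
  expect_equal(s1$mhd_fraction, 5 / (100 * sqrt(2)))

  empty <- segmentation_scores(matrix(FALSE, 10, 10), tgt)
  expect_equal(empty$jaccard, 0)
  expect_equal(empty$dice, 0)
  expect_equal(empty$mcc, 0)
  expect_equal(empty$symmetric_uncertainty, 0)
  expect_true(is.na(empty$mhd_fraction))

  expect_error(segmentation_scores(a, matrix(TRUE, 3, 3)), "mismatched")
  expect_error(segmentation_scores(a, matrix(FALSE, 10, 10)), "empty")
})

test_that("scores agree with brute-force confusion-matrix recomputation", {
  set.seed(31)
  for (i in 1:25) {
    a <- matrix(runif(100) < runif(1, 0.05, 0.9), 10, 10)
    b <- matrix(runif(100) < runif(1, 0.05, 0.9), 10, 10)
    if (!any(b) || !any(a)) next
    s <- segmentation_scores(a, b)
    cf <- brute_confusion(a, b)
    expect_equal(s$jaccard, cf["tp"] / (cf["tp"] + cf["fp"] + cf["fn"]),
                 ignore_attr = TRUE)
    expect_equal(s$dice, 2 * cf["tp"] / (2 * cf["tp"] + cf["fp"] + cf["fn"]),
                 ignore_attr = TRUE)
    mcc_num <- cf["tp"] * cf["tn"] - cf["fp"] * cf["fn"]
    mcc_den <- sqrt(prod(c(cf["tp"] + cf["fp"], cf["tp"] + cf["fn"],
                           cf["tn"] + cf["fp"], cf["tn"] + cf["fn"])))
    if (mcc_den > 0)
      expect_equal(s$mcc, unname(mcc_num / mcc_den))
    expect_lte(s$jaccard, s$dice)
    expect_lte(s$dice, 1)
    expect_gte(s$mcc, -1); expect_lte(s$mcc, 1)
    # MHD against a direct double loop over cell centres
    ga <- which(a, arr.ind = TRUE); gb <- which(b, arr.ind = TRUE)
    dmat <- sqrt(outer(ga[, 1], gb[, 1], "-")^2 + outer(ga[, 2], gb[, 2], "-")^2)
    mhd <- max(mean(apply(dmat, 1, min)), mean(apply(dmat, 2, min)))
    expect_equal(s$mhd_fraction, mhd / sqrt(2 * 100), tolerance = 1e-12)
  }
})

test_that("coverage score counts cells significant for exactly one condition", {
  a <- make_map(1:5)           # 5 cells
  b <- make_map(c(4, 5, 6))    # 3 cells, overlap 2
  expect_equal(coverage_score(list(a, b)), 4L)
  expect_equal(coverage_score(list(a, a)), 0L)
  disjoint <- list(make_map(1:10), make_map(11:30))
  expect_equal(coverage_score(disjoint), 30L)
  # brute force over random map sets
  set.seed(32)
  for (i in 1:20) {
    maps <- lapply(1:4, function(j) matrix(runif(64) < 0.3, 8, 8))
    counts <- Reduce(`+`, maps)
    expect_equal(coverage_score(maps), sum(counts == 1))
  }
})

test_that("scale selection takes the arg-max with ties to the smallest scale", {
  expect_equal(select_scale(c(`10` = 3, `40` = 17, `60` = 17)), 40)
  expect_equal(select_scale(setNames(rep(0, 11), seq(10, 60, 5))), 10)
  expect_equal(select_scale(c(`60` = 17, `40` = 17, `10` = 3)), 40) # order-proof
  expect_equal(select_scale(c(5, 9, 2), scales = c(20, 40, 60)), 40)
  expect_error(select_scale(numeric(0)), "no scores")
})

test_that("prediction standardization thresholds z against the normal upper tail", {
  pred <- matrix(c(0.6, 0.5, 0.7, 0.4), 2, 2)
  v <- matrix(0.0025, 2, 2)
  out <- standardize_prediction(pred, v)
  expect_equal(out$z[1, 1], 2)
  expect_true(out$significant[1, 1]) # 2.0 > 1.6449
  expect_equal(out$z[2, 1], 0)
  expect_false(out$significant[2, 1])
  # doubling the excursion doubles z
  out2 <- standardize_prediction(matrix(0.7, 1, 1), matrix(0.0025, 1, 1))
  expect_equal(out2$z[1, 1], 4)
  # non-positive variance cells are absent
  out3 <- standardize_prediction(matrix(0.9, 1, 1), matrix(0, 1, 1))
  expect_true(is.na(out3$z[1, 1]))
  expect_false(out3$significant[1, 1])
})

test_that("experiment grids enumerate the replication structure", {
  biv <- enumerate_noise_grid(c("bivariate_snowflake", "bivariate_anti"),
                              c(1600, 3200))
  expect_equal(nrow(biv), 1440L)
  uni <- enumerate_noise_grid(c("snowflake", "anti_snowflake", "snowflake_field"),
                              c(600, 1200, 1800))
  expect_equal(nrow(uni), 3240L)
  expect_equal(length(noise_gamma_grid()), 36L)
  expect_equal(nrow(enumerate_interaction_grid()), 60L)
})

test_that("a small noise experiment runs end to end and is seed-reproducible", {
  run <- function() {
    run_noise_experiment("snowflake", 400, gammas = 0.05, n_reps = 2,
                         scales = c(20, 40), seed = 123)
  }
  r1 <- run()
  expect_s3_class(r1, "experiment_result")
  expect_setequal(unique(r1$metric),
                  c("jaccard", "dice", "mcc", "symmetric_uncertainty", "mhd_fraction"))
  expect_true(all(r1$n_reps[r1$metric == "dice"] == 2))
  expect_true(all(r1$sd >= 0, na.rm = TRUE))
  dice <- r1$mean[r1$metric == "dice" & r1$variable == "Z"]
  expect_gt(dice, 0.3) # clean signal at low noise is recovered
  r2 <- run()
  expect_identical(r1, r2)
})

test_that("interaction analyses concentrate Z1 recovery outside R3 as c3 grows", {
  layout <- layout_for_model("interaction")
  spec <- design_spec(c("Z1", "Z2", "Z1*Z2"), intercept = TRUE)
  r3 <- target_map(layout, "Z1*Z2", 0.5)
  share_r3 <- function(c3, seed) {
    obs <- sample_dataset("interaction", 4000, c3, seed = seed, layout = layout)
    maps <- geoparmap:::interaction_term_maps(obs, layout$grid, spec, 60, 0.05)
    c(covered = mean(maps[["Z1"]][r3]),
      share = sum(maps[["Z1"]] & r3) / max(1, sum(maps[["Z1"]])),
      inter = mean(maps[["Z1*Z2"]][r3]))
  }
  lo <- share_r3(0.25, 44)
  hi <- share_r3(0.5, 44)
  # Z1 recovery inside R3 shrinks as the interaction absorbs the variance
  expect_lt(hi[["covered"]], lo[["covered"]] + 1e-9)
  # at c3 = 0.5 most of Z1's significant area lies outside R3
  expect_lt(hi[["share"]], 0.5)
  # the interaction term itself covers most of R3 at c3 = 0.5
  expect_gt(hi[["inter"]], 0.5)
})
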