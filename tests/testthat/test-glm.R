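test_that("one-hot spatial conditions partition the observations", {
  obs2 <- observation_table(cbind(1:4, 1:4),
                            cbind(Z1 = c(0.9, 0.1, 0.7, 0.2),
                                  Z2 = c(0.1, 0.8, 0.9, 0.3)))
  oh <- one_hot_conditions(obs2)
  expect_identical(colnames(oh$values), c("cond_00", "cond_10", "cond_01", "cond_11"))
  # (0.9, 0.1) -> condition (1, 0) -> dummy (0, 1, 0, 0)
  expect_equal(unname(oh$values[1, ]), c(0, 1, 0, 0))
  expect_equal(unname(oh$values[2, ]), c(0, 0, 1, 0))
  expect_equal(unname(oh$values[3, ]), c(0, 0, 0, 1))
  expect_equal(unname(oh$values[4, ]), c(1, 0, 0, 0))
  expect_true(all(rowSums(oh$values) == 1))

  obs1 <- observation_table(cbind(1:3, 1:3), cbind(Z = c(0, 1, 0.5)))
  oh1 <- one_hot_conditions(obs1)
  expect_equal(unname(oh1$values[1, ]), c(1, 0))
  # a value exactly at the threshold does not exceed it
  expect_equal(unname(oh1$values[3, ]), c(1, 0))
  expect_true(all(rowSums(oh1$values) == 1))
})

test_that("design matrices respect term order, interactions and rank", {
  obs <- observation_table(cbind(1:6, 1:6),
                           cbind(y1 = c(1, 0, 1, 1, 0, 0),
                                 y2 = c(0.5, 1.5, 2, 0, 1, 3)))
  d <- build_design(obs, design_spec(c("y1", "y2", "y1*y2"), intercept = TRUE))
  expect_identical(d$term_names, c("intercept", "y1", "y2", "y1*y2"))
  expect_equal(d$X[, "y1*y2"], obs$values[, "y1"] * obs$values[, "y2"])
  expect_equal(d$rank, 4L)

  d0 <- build_design(obs, design_spec(character(0), intercept = TRUE))
  expect_equal(unname(d0$X), matrix(1, 6, 1))
  expect_equal(d0$rank, 1L)

  # constant variable plus intercept: collinear, rank < Q reported
  obs_c <- observation_table(cbind(1:4, 1:4), cbind(a = rep(2, 4), b = 1:4))
  dc <- build_design(obs_c, design_spec(c("a", "b"), intercept = TRUE))
  expect_lt(dc$rank, 3L)

  # full one-hot plus intercept is rejected with advice
  oh <- one_hot_conditions(observation_table(cbind(1:4, 1:4), cbind(Z = c(0, 1, 0, 1))))
  expect_error(build_design(oh, design_spec(c("cond_0", "cond_1"), intercept = TRUE)),
               "drop the intercept")
  expect_error(build_design(obs, design_spec("nope")), "unknown variable")
})

test_that("mass-univariate OLS matches the per-cell textbook solve", {
  set.seed(7)
  X <- cbind(1, matrix(rnorm(8 * 2), 8, 2))
  Y <- matrix(rnorm(8 * 25), 8, 25)
  g <- grid_spec(5, 5)
  fit <- fit_mass_univariate(Y, X, g)
  oracle <- brute_force_ols(X, Y, contrast = c(0, 1, 0))
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-10)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-10)
  expect_equal(fit$nu, oracle$nu)
  t_map <- contrast_t_map(fit, c(0, 1, 0))
  expect_equal(as.vector(t_map), oracle$t, tolerance = 1e-10)
  # X beta + residual reproduces the response
  expect_equal(X %*% fit$beta + fit$residuals, Y, tolerance = 1e-12)
})

test_that("t maps are invariant to response scaling and observation order", {
  set.seed(8)
  X <- cbind(1, rnorm(10))
  Y <- matrix(rexp(10 * 9), 10, 9)
  g <- grid_spec(3, 3)
  t1 <- contrast_t_map(fit_mass_univariate(Y, X, g), c(0, 1))
  t2 <- contrast_t_map(fit_mass_univariate(1000 * Y, X, g), c(0, 1))
  expect_equal(t1, t2, tolerance = 1e-8)
  perm <- sample(10)
  t3 <- contrast_t_map(fit_mass_univariate(Y[perm, ], X[perm, ], g), c(0, 1))
  expect_equal(t1, t3, tolerance = 1e-10)
})

test_that("degenerate and null-contrast cells behave as specified", {
  g <- grid_spec(2, 2)
  # two-condition one-hot design, responses identical across observations:
  # betas equal the shared response, residuals vanish, t is flagged absent
  X <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  Y <- matrix(rep(c(0.3, 0.7, 0, 1), each = 4), 4, 4)
  fit <- fit_mass_univariate(Y, X, g)
  expect_equal(unname(fit$beta), rbind(Y[1, ], Y[1, ]))
  expect_equal(max(abs(fit$residuals)), 0)
  expect_true(all(fit$degenerate))
  expect_true(all(is.na(contrast_t_map(fit, c(1, -1)))))

  # group means equal by construction -> c'beta = 0 -> t identically 0
  e <- c(-1, 1, -2, 2)
  Y2 <- matrix(5, 4, 4) + matrix(e, 4, 4)
  fit2 <- fit_mass_univariate(Y2, X, g)
  expect_equal(unname(contrast_t_map(fit2, c(1, -1))), matrix(0, 2, 2))
  # flipping the contrast negates the map
  t_a <- contrast_t_map(fit2, c(1, 0))
  expect_equal(contrast_t_map(fit2, c(-1, 0)), -t_a)
})

test_that("single-regressor ones design reproduces the one-sample t test", {
  set.seed(9)
  Y <- matrix(rnorm(12 * 4, mean = 0.4), 12, 4)
  fit <- fit_mass_univariate(Y, matrix(1, 12, 1), grid_spec(2, 2))
  t_map <- contrast_t_map(fit, 1)
  for (m in 1:4)
    expect_equal(as.vector(t_map)[m], unname(t.test(Y[, m])$statistic),
                 tolerance = 1e-10)
})

test_that("inestimable and invalid contrasts are rejected", {
  set.seed(10)
  X <- cbind(1, c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 0)) # rank 2
  Y <- matrix(rnorm(5 * 4), 5, 4)
  expect_warning(fit <- fit_mass_univariate(Y, X, grid_spec(2, 2)),
                 "rank deficient")
  expect_error(contrast_t_map(fit, c(0, 1, 0)), "not estimable")
  expect_error(contrast_t_map(fit, c(1, 2)), "length")
})

test_that("condition-vs-rest contrasts sum to zero and weight the rest by prevalence", {
  cm <- condition_contrasts(4) # equal weights
  expect_equal(rowSums(cm), rep(0, 4))
  expect_equal(diag(cm), rep(1, 4))
  expect_equal(cm[1, -1], rep(-1 / 3, 3))
  cw <- condition_contrasts(c(a = 100, b = 50, c = 50))
  expect_equal(unname(rowSums(cw)), rep(0, 3))
  expect_equal(unname(cw[2, ]), c(-100 / 150, 1, -50 / 150))
  expect_error(condition_contrasts(c(3, 0)), "must have observations")
})

test_that("streaming fit and smoothness agree with the dense path", {
  set.seed(12)
  g <- grid_spec(30, 25)
  n <- 40
  obs <- observation_table(cbind(runif(n, 2, 28), runif(n, 2, 23)),
                           cbind(g1 = rbinom(n, 1, 0.5)))
  oh <- one_hot_conditions(obs)
  k <- smoothing_kernel(8)
  X <- oh$values
  Y <- geoparmap:::rasterize_all(oh, k, g)
  dense <- fit_mass_univariate(Y, X, g)
  sm_dense <- estimate_fwhm(standardize_residuals(dense), g)
  stream <- geoparmap:::stream_fit_smoothness(X, oh, k, g, chunk_cells = 7 * 750)
  expect_equal(stream$fit$beta, dense$beta, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(stream$fit$sigma2, dense$sigma2, tolerance = 1e-9)
  expect_equal(stream$fit$degenerate, dense$degenerate)
  expect_equal(stream$smoothness$fwhm_x, sm_dense$fwhm_x, tolerance = 1e-6)
  expect_equal(stream$smoothness$fwhm_y, sm_dense$fwhm_y, tolerance = 1e-6)
})
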