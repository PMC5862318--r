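test_that("fold assignment is balanced, bounded and reproducible", {
  f <- assign_folds(10, 10, seed = 1)
  expect_true(all(table(f) == 1))
  f2 <- assign_folds(95, 10, seed = 2)
  sizes <- as.integer(table(f2))
  expect_setequal(sizes, c(9L, 10L))
  expect_equal(sum(sizes == 10L), 5)
  expect_identical(assign_folds(50, 5, seed = 3), assign_folds(50, 5, seed = 3))
  expect_error(assign_folds(5, 6), "exceed")
})

# 12-row fixture: an intercept-only learner's out-of-fold prediction must be
# the training mean of the other folds, hand-computed by an explicit loop.
test_that("out-of-fold predictions match the per-fold training-mean oracle", {
  u <- c(10, 20, 30, 40, 100, 110, 120, 130, 5, 15, 25, 35)
  data <- tibble::tibble(
    unprofit = u,
    cls_001 = rep(0L, 12), cls_002 = rep(0L, 12)  # no signal: mean fits
  )
  folds <- rep(1:3, each = 4)
  specs <- learner_library(algorithms = "glm", sets = "full")
  cvp <- cv_predictions(data, specs, folds = folds)
  oracle <- numeric(12)
  for (i in 1:12) oracle[i] <- mean(u[folds != folds[i]])
  expect_equal(unname(cvp$Z[, 1]), oracle, tolerance = 1e-10)
  expect_equal(dim(cvp$Z), c(12L, 1L))
})

test_that("perturbing an outcome never changes that row's out-of-fold prediction", {
  co <- small_cohort(n = 120, seed = 51)
  specs <- fast_specs()
  folds <- assign_folds(120, 4, seed = 9)
  z1 <- cv_predictions(co, specs, folds = folds, seed = 5)$Z
  for (i in c(3, 77)) {
    co2 <- co
    co2$unprofit[i] <- co2$unprofit[i] + 1e6
    z2 <- cv_predictions(co2, specs, folds = folds, seed = 5)$Z
    expect_equal(z2[i, ], z1[i, ], tolerance = 1e-10)
  }
})

test_that("ensemble weights solve the simplex least-squares problem", {
  # K = 1 is forced to weight one
  u <- withr::with_seed(52, rnorm(30))
  expect_equal(unname(estimate_weights(u, matrix(u, ncol = 1))$alpha), 1)

  # an exact predictor plus independent noise gets all the weight
  z <- cbind(truth = u, noise = withr::with_seed(53, rnorm(30)))
  w <- estimate_weights(u, z)
  oracle <- grid_search_simplex(u, z, step = 0.001)
  expect_equal(unname(w$alpha), oracle$alpha, tolerance = 1e-3)
  expect_equal(unname(w$alpha), c(1, 0), tolerance = 1e-3)

  # K = 3 random instances agree with the dense grid oracle
  for (seed in 1:4) {
    zz <- withr::with_seed(seed, matrix(rnorm(30 * 3, 0, 1), 30, 3))
    uu <- withr::with_seed(seed + 60, zz %*% c(0.2, 0.5, 0.3) + rnorm(30, 0, 0.3))
    w <- estimate_weights(as.numeric(uu), zz)
    oracle <- grid_search_simplex(as.numeric(uu), zz, step = 0.01)
    expect_lte(w$objective, oracle$objective + 1e-10)
    expect_lt(max(abs(unname(w$alpha) - oracle$alpha)), 0.011)
  }
})

test_that("weights are convex and never worse than any single learner", {
  for (seed in 1:6) {
    n <- 40
    z <- withr::with_seed(seed, matrix(rnorm(n * 4, 0, 2), n, 4))
    u <- withr::with_seed(seed + 10, rnorm(n, 0, 2))
    w <- estimate_weights(u, z)
    expect_true(all(w$alpha >= -1e-12))
    expect_equal(sum(w$alpha), 1, tolerance = 1e-10)
    expect_lte(w$objective, min(w$learner_risks) + 1e-8)
  }
})

test_that("identical prediction columns give uniform weights with a warning", {
  u <- withr::with_seed(54, rnorm(25))
  z <- matrix(rep(u * 0.5, 3), ncol = 3)
  expect_warning(w <- estimate_weights(u, z), "identical")
  expect_equal(unname(w$alpha), rep(1 / 3, 3))
})

test_that("the default library instantiates fifteen learners with 10-fold CV", {
  specs <- learner_library()
  expect_equal(nrow(specs), 15)
  expect_equal(anyDuplicated(specs$id), 0)
  expect_setequal(unique(specs$algorithm), c("nnet", "lasso", "ridge", "tree", "glm"))
  expect_setequal(unique(specs$variable_set), c("full", "groups", "screened"))
  expect_true(all(grepl("\\.(f|g|l)$", specs$id)))
  expect_equal(formals(fit_super_learner)$v, 10)
  expect_equal(formals(nested_cv_evaluate)$v_outer, 10)
  expect_equal(formals(nested_cv_evaluate)$v_inner, 10)
})

test_that("the ensemble prediction is the stated convex combination", {
  co <- small_cohort(n = 250, seed = 55)
  sl <- fit_super_learner(co, fast_specs(), v = 4, seed = 6)
  expect_true(all(sl$alpha >= -1e-12))
  expect_equal(sum(sl$alpha), 1, tolerance = 1e-10)

  p_learners <- predict(sl, co, learners = TRUE)
  p <- predict(sl, co)
  expect_equal(p, as.numeric(p_learners %*% sl$alpha))
  # convex-combination bounds per row
  expect_true(all(p <= apply(p_learners, 1, max) + 1e-8))
  expect_true(all(p >= apply(p_learners, 1, min) - 1e-8))

  # degenerate weight at one learner reproduces that learner exactly
  sl$alpha[] <- 0
  sl$alpha["tree.g"] <- 1
  expect_equal(predict(sl, co), unname(p_learners[, "tree.g"]))
})

test_that("super learner runs are reproducible end to end", {
  co <- small_cohort(n = 200, seed = 56)
  s1 <- fit_super_learner(co, fast_specs(), v = 3, seed = 8)
  s2 <- fit_super_learner(co, fast_specs(), v = 3, seed = 8)
  expect_identical(s1$alpha, s2$alpha)
  expect_identical(predict(s1, co), predict(s2, co))
  expect_identical(s1$cv$Z, s2$cv$Z)
})

test_that("tidy and glance summarize the fit", {
  co <- small_cohort(n = 150, seed = 57)
  sl <- fit_super_learner(co, fast_specs(), v = 3, seed = 2)
  td <- tidy(sl)
  expect_setequal(names(td), c("id", "algorithm", "variable_set", "weight", "cv_risk"))
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$weight), 1, tolerance = 1e-10)
  gl <- glance(sl)
  expect_equal(gl$n, 150)
  expect_equal(gl$k, 4)
})
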