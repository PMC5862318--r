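spec_for <- function(algorithm, set = "full") {
  learner_library(algorithms = algorithm, sets = set)
}

test_that("main-terms linear regression interpolates noiseless linear data", {
  x <- binary_design(60, 5, seed = 2)
  beta <- c(100, -250, 40, 0, 900)
  u <- as.numeric(x %*% beta) + 50
  fit <- fit_learner(spec_for("glm"), x, u)
  expect_equal(predict(fit, x), u, tolerance = 1e-8)
})

test_that("collinear columns are handled and leave predictions unchanged", {
  x <- binary_design(80, 4, seed = 3)
  x <- cbind(x, cls_dup = x[, 1])  # exact copy
  u <- withr::with_seed(4, rnorm(80, 0, 10) + 30 * x[, 2])
  fit <- fit_learner(spec_for("glm"), x, u)
  fit_base <- fit_learner(spec_for("glm"), x[, 1:4], u)
  expect_equal(predict(fit, x), predict(fit_base, x[, 1:4]), tolerance = 1e-8)
})

test_that("ridge matches the closed form on an orthonormal design", {
  n <- 200
  q <- orthonormal_design(n, 6)
  u <- withr::with_seed(6, rnorm(n, 0, 2) + 3 * q[, 1] - 5 * q[, 4])
  fit <- fit_learner(spec_for("ridge"), q, u, seed = 1)
  path <- fit$fit$cv$glmnet.fit
  z <- as.numeric(crossprod(q, u - mean(u)))
  # glmnet standardizes the outcome internally, so its ridge solution at
  # lambda equals the closed form (X'X + n*lambda/sigma_y I)^-1 X'U on an
  # orthonormal design, sigma_y the population sd of the outcome
  sig <- sqrt(mean((u - mean(u))^2))
  for (j in seq(5, length(path$lambda), by = 20)) {
    lam <- path$lambda[j]
    oracle <- z / (1 + n * lam / sig)
    expect_equal(as.numeric(path$beta[, j]), oracle, tolerance = 1e-4)
  }
})

test_that("lasso matches the soft-threshold closed form on an orthonormal design", {
  n <- 200
  q <- orthonormal_design(n, 6, seed = 8)
  u <- withr::with_seed(9, rnorm(n, 0, 1) + 4 * q[, 2] - 2 * q[, 5])
  fit <- fit_learner(spec_for("lasso"), q, u, seed = 1)
  path <- fit$fit$cv$glmnet.fit
  z <- as.numeric(crossprod(q, u - mean(u)))
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (j in seq(3, length(path$lambda), by = 15)) {
    lam <- path$lambda[j]
    expect_equal(as.numeric(path$beta[, j]), soft(z, n * lam), tolerance = 1e-4)
  }
})

test_that("the ANOVA tree finds the exhaustive-search best first split", {
  x <- binary_design(300, 5, prob = 0.4, seed = 12)
  u <- withr::with_seed(13, 1000 * x[, 3] + rnorm(300, 0, 1))
  # independent oracle: exhaustive search for the split maximizing
  # between-group sum of squares over the binary columns
  ss <- vapply(seq_len(ncol(x)), function(j) {
    g1 <- u[x[, j] == 1]; g0 <- u[x[, j] == 0]
    if (length(g1) == 0 || length(g0) == 0) return(0)
    length(g1) * (mean(g1) - mean(u))^2 + length(g0) * (mean(g0) - mean(u))^2
  }, numeric(1))
  best <- colnames(x)[which.max(ss)]
  expect_identical(best, "cls_003")

  fit <- fit_learner(spec_for("tree"), x, u)
  root_var <- as.character(fit$fit$tree$frame$var[1])
  expect_identical(root_var, best)
  # predictions are constant within each side of the step
  p <- predict(fit, x)
  expect_equal(unname(p[x[, 3] == 1]), rep(mean(u[x[, 3] == 1]), sum(x[, 3])),
               tolerance = 1e-6)
})

test_that("single-variable step data yields a fold-constant tree fit", {
  x <- matrix(rep(c(0, 1), each = 50), ncol = 1,
              dimnames = list(NULL, "cls_001"))
  u <- c(rep(0, 50), rep(100, 50)) + withr::with_seed(14, rnorm(100, 0, 0.1))
  fit <- fit_learner(spec_for("tree"), x, u)
  p <- predict(fit, x)
  expect_equal(length(unique(round(p, 6))), 2)
  expect_equal(sort(unique(round(p, 2))),
               round(c(mean(u[1:50]), mean(u[51:100])), 2))
})

test_that("constant outcomes degrade to a mean fit instead of crashing", {
  x <- binary_design(40, 3, seed = 15)
  for (alg in c("glm", "lasso", "ridge", "tree", "nnet")) {
    expect_warning(fit <- fit_learner(spec_for(alg), x, rep(7, 40)),
                   "mean fit")
    expect_equal(predict(fit, x), rep(7, 40))
  }
})

test_that("fully penalized lasso predicts a constant at the intercept", {
  # constant predictors carry no signal: every coefficient is zero
  x <- matrix(1, 50, 3, dimnames = list(NULL, paste0("cls_00", 1:3)))
  u <- withr::with_seed(16, rnorm(50, 500, 10))
  fit <- fit_learner(spec_for("lasso"), x, u, seed = 2)
  expect_equal(predict(fit, x), rep(mean(u), 50), tolerance = 1e-6)
})

test_that("predictions are invariant to column permutation", {
  x <- binary_design(150, 6, seed = 17)
  u <- withr::with_seed(18, rnorm(150, 0, 5) + 200 * x[, 2] - 80 * x[, 5])
  perm <- c(4, 1, 6, 2, 5, 3)
  for (alg in c("glm", "lasso", "ridge", "tree")) {
    f1 <- fit_learner(spec_for(alg), x, u, seed = 3)
    f2 <- fit_learner(spec_for(alg), x[, perm], u, seed = 3)
    # exact for glm/tree; penalized fits agree to solver tolerance
    expect_equal(predict(f1, x), predict(f2, x[, perm]), tolerance = 1e-4)
  }
})

test_that("refits with identical seed and data are reproducible", {
  x <- binary_design(120, 8, seed = 19)
  u <- withr::with_seed(20, rnorm(120, 0, 3) + 50 * x[, 1])
  for (alg in c("nnet", "lasso", "ridge")) {
    f1 <- fit_learner(spec_for(alg), x, u, seed = 42)
    f2 <- fit_learner(spec_for(alg), x, u, seed = 42)
    expect_identical(predict(f1, x), predict(f2, x))
  }
})

test_that("the neural net has one two-unit hidden layer and learns signal", {
  x <- binary_design(400, 4, prob = 0.5, seed = 21)
  u <- withr::with_seed(22, 1000 * x[, 1] + rnorm(400, 0, 10))
  fit <- fit_learner(spec_for("nnet"), x, u, seed = 5)
  expect_equal(fit$fit$net$n, c(4, 2, 1))  # input - hidden - output
  p <- predict(fit, x)
  expect_lt(mean((u - p)^2), var(u) * 0.2)
})

test_that("prediction rejects mismatched columns and names the offenders", {
  x <- binary_design(50, 3, seed = 23)
  u <- withr::with_seed(24, rnorm(50))
  fit <- fit_learner(spec_for("glm"), x, u)
  bad <- x[, 1:2]
  expect_error(predict(fit, bad), "cls_003")
  # column order does not matter
  expect_equal(predict(fit, x[, c(3, 1, 2)]), predict(fit, x))
})
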