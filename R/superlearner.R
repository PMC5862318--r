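#' Random balanced fold assignment
#'
#' Uniformly random partition of `n` rows into `v` folds whose sizes differ
#' by at most one, reproducible from `seed`.
#'
#' @param n Number of rows.
#' @param v Number of folds, `2 <= v <= n`.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:v` with attribute `"seed"`.
#' @export
assign_folds <- function(n, v, seed = 1) {
  n <- assert_scalar_count(n, "n", 2L)
  v <- assert_scalar_count(v, "v", 2L)
  if (v > n) abort("`v` must not exceed `n`.")
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(v), n)))
  attr(folds, "seed") <- seed
  folds
}

# The design matrix shared by all learners: every indicator column, as a
# dense numeric matrix (subset by column per variable set).
design_matrix <- function(data) {
  cols <- indicator_columns(data)
  if (length(cols) == 0) abort("No indicator columns found in `data`.")
  x <- as.matrix(data[cols])
  storage.mode(x) <- "double"
  x
}

resolve_sets <- function(data, vocab = cohort_vocabulary(data)) {
  cols <- indicator_columns(data)
  if (!is.null(vocab)) {
    variable_sets(vocab, columns = cols)
  } else {
    list(
      full = cols[is_class_col(cols) | is_generic_col(cols) | is_maintenance_col(cols)],
      groups = cols[is_group_col(cols) | is_generic_col(cols) | is_maintenance_col(cols)]
    )
  }
}

resolve_forced <- function(data, vocab = cohort_vocabulary(data)) {
  if (is.null(vocab)) character() else intersect(vocab$forced_ids, names(data))
}

outcome_vector <- function(data) {
  if (!"unprofit" %in% names(data)) {
    abort("`data` has no `unprofit` column; run add_plan_payments() first.")
  }
  data$unprofit
}

# Row-subset a cohort tibble without losing its vocabulary attributes.
subset_cohort <- function(data, rows) {
  out <- data[rows, , drop = FALSE]
  attr(out, "vocabulary") <- attr(data, "vocabulary")
  attr(out, "cohort_config") <- attr(data, "cohort_config")
  out
}

#' Out-of-fold prediction matrix
#'
#' Step one of the ensemble: every candidate learner is fit on each fold's
#' training rows and predicts the fold's validation rows, filling the
#' n-by-K matrix `Z` of cross-validated predictions. Row `i` of `Z` is
#' always produced by fits that never saw row `i`'s outcome. Learners using
#' the screened variable set share one screening per fold, computed on that
#' fold's training rows only.
#'
#' @param data Cohort tibble with an `unprofit` column.
#' @param specs Learner library tibble ([learner_library()]).
#' @param folds Fold labels from [assign_folds()] (or `NULL` to draw them
#'   from `seed` with `v` folds).
#' @param v Number of folds when `folds` is `NULL`.
#' @param seed Integer run seed.
#' @param control An [sl_control()].
#' @return Object of class `cv_predictions`: list with `Z` (matrix, one
#'   column per learner id), `folds`, `screened` (per-fold
#'   `variable_screen`s), `specs`.
#' @export
cv_predictions <- function(data, specs, folds = NULL, v = 10, seed = 1,
                           control = sl_control()) {
  if (nrow(specs) == 0) abort("`specs` must contain at least one learner.")
  u <- outcome_vector(data)
  n <- nrow(data)
  if (is.null(folds)) folds <- assign_folds(n, v, substream(seed, "folds"))
  x_all <- design_matrix(data)
  sets <- resolve_sets(data)
  forced <- resolve_forced(data)

  z <- matrix(NA_real_, n, nrow(specs), dimnames = list(NULL, specs$id))
  screened <- list()
  need_screen <- any(specs$variable_set == "screened")

  for (fold in sort(unique(folds))) {
    tr <- which(folds != fold)
    va <- which(folds == fold)
    cols_l <- NULL
    if (need_screen) {
      scr <- screen_within_fold(x_all[, sets$full, drop = FALSE], u, tr,
                                cap = control$screen_cap, forced = forced,
                                control = control)
      screened[[as.character(fold)]] <- scr
      cols_l <- scr$ids
    }
    for (k in seq_len(nrow(specs))) {
      spec <- specs[k, ]
      cols <- switch(spec$variable_set,
        full = sets$full, groups = sets$groups, screened = cols_l
      )
      if (length(cols) == 0) {
        z[va, k] <- mean(u[tr])
        next
      }
      fit <- fit_learner(spec, x_all[tr, cols, drop = FALSE], u[tr],
                         seed = substream(seed, "fit", fold, spec$id),
                         control = control)
      z[va, k] <- predict(fit, x_all[va, cols, drop = FALSE])
    }
  }

  structure(
    list(Z = z, folds = folds, screened = screened, specs = specs),
    class = "cv_predictions"
  )
}

# Euclidean projection onto the probability simplex (sort-based).
project_simplex <- function(y) {
  s <- sort(y, decreasing = TRUE)
  css <- cumsum(s)
  rho <- max(which(s - (css - 1) / seq_along(s) > 0))
  pmax(y - (css[rho] - 1) / rho, 0)
}

#' Estimate convex ensemble weights
#'
#' Step two of the ensemble: find the convex combination
#' \eqn{\alpha \ge 0,\ \sum_k \alpha_k = 1} minimizing the cross-validated
#' squared error \eqn{\sum_i (U_i - \sum_k \alpha_k Z_{ik})^2} — a
#' regression of the outcome on the out-of-fold prediction matrix
#' restricted to the simplex. Solved as a simplex-constrained quadratic
#' program: non-negative least squares (Lawson–Hanson) normalized to sum
#' one provides the starting point, refined by accelerated projected
#' gradient descent to the global optimum of the convex problem. The
#' resulting ensemble's CV objective is never worse than any single
#' learner's.
#'
#' @param u Outcome vector ($).
#' @param z `cv_predictions` object or the bare n-by-K matrix.
#' @return Object of class `ensemble_weights`: `alpha` (named, sums to 1),
#'   `objective` (mean squared CV error of the ensemble), `learner_risks`.
#' @export
estimate_weights <- function(u, z) {
  if (inherits(z, "cv_predictions")) z <- z$Z
  z <- as.matrix(z)
  if (nrow(z) != length(u)) abort("`u` and `z` must agree in length.")
  if (!all(is.finite(z))) abort("`z` must be finite.")
  k <- ncol(z)
  ids <- colnames(z) %||% paste0("learner_", seq_len(k))
  n <- nrow(z)

  if (k == 1L) {
    alpha <- stats::setNames(1, ids)
  } else if (max(abs(z - z[, 1])) < 1e-10) {
    warn("All learner prediction columns are identical; using uniform weights.")
    alpha <- stats::setNames(rep(1 / k, k), ids)
  } else {
    g <- crossprod(z) / n
    b <- crossprod(z, u) / n
    init <- tryCatch({
      nn <- pracma::lsqnonneg(z, u)$x
      if (sum(nn) > 1e-12) nn / sum(nn) else rep(1 / k, k)
    }, error = function(e) rep(1 / k, k))
    lips <- 2 * max(eigen(g, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
    a <- project_simplex(init)
    y <- a
    t_k <- 1
    for (iter in seq_len(20000)) {
      grad <- 2 * (g %*% y - b)
      a_new <- project_simplex(as.numeric(y - grad / lips))
      t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      y <- a_new + ((t_k - 1) / t_new) * (a_new - a)
      if (max(abs(a_new - a)) < 1e-14 && iter > 10) {
        a <- a_new
        break
      }
      a <- a_new
      t_k <- t_new
    }
    alpha <- stats::setNames(as.numeric(a), ids)
  }

  structure(
    list(
      alpha = alpha,
      objective = mean((u - as.numeric(z %*% alpha))^2),
      learner_risks = stats::setNames(colMeans((u - z)^2), ids)
    ),
    class = "ensemble_weights"
  )
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat("<ensemble_weights>\n")
  w <- x$alpha[x$alpha > 1e-4]
  print(round(w[order(-w)], 3))
  cat(sprintf("CV objective: %.4g\n", x$objective))
  invisible(x)
}

#' Fit the super learner ensemble
#'
#' The full three-step procedure: (1) out-of-fold predictions of every
#' candidate learner under `v`-fold cross-validation, (2) convex ensemble
#' weights minimizing cross-validated squared error, (3) refit of every
#' learner on the full data (learners on the screened set re-screen on the
#' full data). The ensemble predictor is
#' \eqn{\hat\Psi_{SL}(x) = \sum_k \hat\alpha_k \hat\Psi_k(x)}.
#'
#' @param data Cohort tibble with an `unprofit` column (see
#'   [add_plan_payments()]).
#' @param specs Learner library (default: all 15 of [learner_library()]).
#' @param v Folds for weight estimation (default 10).
#' @param seed Integer run seed.
#' @param control An [sl_control()].
#' @return Object of class `super_learner` with [predict()], [tidy()] and
#'   [glance()] methods.
#' @export
fit_super_learner <- function(data, specs = learner_library(), v = 10,
                              seed = 1, control = sl_control()) {
  u <- outcome_vector(data)
  cvp <- cv_predictions(data, specs, v = v, seed = seed, control = control)
  weights <- estimate_weights(u, cvp$Z)

  x_all <- design_matrix(data)
  sets <- resolve_sets(data)
  forced <- resolve_forced(data)
  screened_full <- NULL
  if (any(specs$variable_set == "screened")) {
    screened_full <- screen_variables(
      x_all[, sets$full, drop = FALSE], u,
      cap = control$screen_cap, forced = forced, control = control
    )
  }

  learners <- list()
  alpha <- weights$alpha
  for (k in seq_len(nrow(specs))) {
    spec <- specs[k, ]
    cols <- switch(spec$variable_set,
      full = sets$full, groups = sets$groups, screened = screened_full$ids
    )
    learners[[spec$id]] <- tryCatch(
      fit_learner(spec, x_all[, cols, drop = FALSE], u,
                  seed = substream(seed, "refit", spec$id), control = control),
      error = function(e) {
        warn(sprintf(
          "Learner %s failed on the full data and was dropped (weight renormalized): %s",
          spec$id, conditionMessage(e)
        ))
        NULL
      }
    )
  }
  kept <- !vapply(learners, is.null, logical(1))
  learners <- learners[kept]
  alpha <- alpha[names(learners)]
  if (sum(alpha) <= 0) alpha[] <- 1 / length(alpha) else alpha <- alpha / sum(alpha)

  structure(
    list(
      learners = learners,
      weights = weights,
      alpha = alpha,
      cv = cvp,
      screened_full = screened_full,
      specs = specs,
      v = v,
      seed = seed,
      control = control,
      n = nrow(data)
    ),
    class = "super_learner"
  )
}

#' Predict from a fitted super learner
#'
#' @param object A `super_learner`.
#' @param newdata Cohort tibble (or matrix) containing all indicator
#'   columns the learners were trained on.
#' @param learners If `TRUE`, return the n-by-K matrix of per-learner
#'   predictions instead of the ensemble vector.
#' @param ... Unused.
#' @return Numeric vector of ensemble $ predictions (or a matrix).
#' @export
predict.super_learner <- function(object, newdata, learners = FALSE, ...) {
  x <- if (is.matrix(newdata)) newdata else {
    cols <- indicator_columns(newdata)
    m <- as.matrix(newdata[cols]); storage.mode(m) <- "double"; m
  }
  p <- vapply(
    object$learners,
    function(l) predict(l, x[, l$columns, drop = FALSE]),
    numeric(nrow(x))
  )
  if (nrow(x) == 1L) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(object$learners)))
  if (learners) return(p)
  as.numeric(p %*% object$alpha)
}

#' @export
print.super_learner <- function(x, ...) {
  cat(sprintf("<super_learner> %d learners, %d-fold CV, n = %d\n",
              length(x$learners), x$v, x$n))
  w <- x$alpha[x$alpha > 1e-3]
  cat("weights: ", paste(sprintf("%s = %.2f", names(w)[order(-w)],
                                 sort(w, decreasing = TRUE)), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a super learner fit
#'
#' @param x A `super_learner`.
#' @param ... Unused.
#' @return Tibble with one row per learner: `id`, `algorithm`,
#'   `variable_set`, `weight`, `cv_risk` ($^2 cross-validated squared
#'   error of the learner alone).
#' @method tidy super_learner
#' @export
tidy.super_learner <- function(x, ...) {
  specs <- x$specs[x$specs$id %in% names(x$learners), ]
  tibble(
    id = specs$id,
    algorithm = specs$algorithm,
    variable_set = specs$variable_set,
    weight = as.numeric(x$alpha[specs$id]),
    cv_risk = as.numeric(x$weights$learner_risks[specs$id])
  )
}

#' Glance at a super learner fit
#'
#' @param x A `super_learner`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `k`, `v`, `cv_objective`, `seed`.
#' @method glance super_learner
#' @export
glance.super_learner <- function(x, ...) {
  tibble(
    n = x$n, k = length(x$learners), v = x$v,
    cv_objective = x$weights$objective, seed = x$seed
  )
}
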