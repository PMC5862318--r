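#' Cross-validated mean squared error
#'
#' \eqn{n^{-1} \sum_i (U_i - z_i)^2} over out-of-fold predictions.
#'
#' @param u Observed outcomes ($).
#' @param z Out-of-fold predictions ($), same length.
#' @return Scalar MSE in $^2.
#' @export
cv_mse <- function(u, z) {
  if (length(u) != length(z)) abort("`u` and `z` must have equal length.")
  if (length(u) < 1L) abort("Empty input.")
  mean((u - z)^2)
}

#' Cross-validated R-squared
#'
#' \eqn{1 - \sum_i (U_i - z_i)^2 / \sum_i (U_i - \bar U)^2}. Negative for
#' predictors worse than the outcome mean; reported as-is, never truncated.
#'
#' @inheritParams cv_mse
#' @return Scalar fraction (may be negative).
#' @export
cv_r2 <- function(u, z) {
  if (length(u) != length(z)) abort("`u` and `z` must have equal length.")
  sst <- sum((u - mean(u))^2)
  if (sst <= 0) abort("`u` is constant: R-squared is undefined.")
  1 - sum((u - z)^2) / sst
}

#' Relative efficiency of a learner against the ensemble
#'
#' \eqn{\mathrm{RE}_k = \mathrm{CV}\,R^2_k / \mathrm{CV}\,R^2_{SL}}.
#'
#' @param r2_k Learner CV R-squared values (vectorized).
#' @param r2_sl The ensemble's CV R-squared.
#' @return Fractions; `NA` with a warning when `r2_sl == 0`.
#' @export
relative_efficiency <- function(r2_k, r2_sl) {
  stopifnot(length(r2_sl) == 1L)
  if (is.na(r2_sl) || r2_sl == 0) {
    warn("Ensemble CV R-squared is zero: relative efficiency undefined.")
    return(rep(NA_real_, length(r2_k)))
  }
  r2_k / r2_sl
}

#' Residual diagnostics with robust outlier flagging
#'
#' Residuals `u - predictions`; entries farther than `mad_mult` median
#' absolute deviations from the median residual are flagged extreme. With
#' heavy-tailed health spending, a handful of multimillion-dollar enrollees
#' typically dominate the flags.
#'
#' @param u Observed outcomes ($).
#' @param predictions Ensemble predictions ($), same length.
#' @param mad_mult Robust threshold multiplier (default 6).
#' @return Tibble `id`, `residual`, `extreme`, with a `summary` attribute
#'   (mean, sd, median, mad, threshold, n_extreme).
#' @export
residual_report <- function(u, predictions, mad_mult = 6) {
  if (length(u) != length(predictions)) abort("Length mismatch.")
  res <- u - predictions
  med <- median(res)
  madv <- mad(res)
  extreme <- abs(res - med) > mad_mult * madv
  out <- tibble(id = seq_along(res), residual = res, extreme = extreme)
  attr(out, "summary") <- list(
    mean = mean(res), sd = sd(res), median = med, mad = madv,
    threshold = mad_mult * madv, n_extreme = sum(extreme)
  )
  out
}

#' Nested cross-validation of the whole super learner
#'
#' Honest evaluation of the complete pipeline: an outer `v_outer`-fold
#' cross-validation in which each outer training set runs the *entire*
#' ensemble procedure — inner fold assignment, per-fold variable screening,
#' weight estimation and full refit — and predicts its outer validation
#' fold. Metrics are pooled over all outer-fold predictions (single-sum
#' formulas), for the ensemble and for every candidate learner refit on
#' each outer training set.
#'
#' @param data Cohort tibble with an `unprofit` column.
#' @param specs Learner library tibble.
#' @param v_outer,v_inner Outer / inner fold counts (defaults 10 and 10).
#' @param seed Integer run seed; outer folds, inner folds and learner fits
#'   use independent substreams.
#' @param control An [sl_control()].
#' @return Object of class `sl_evaluation`: `metrics` (tibble with one row
#'   per learner plus one for the super learner: `cv_mse`, `cv_r2`,
#'   `rel_efficiency`), `predictions` (per-enrollee out-of-fold tibble),
#'   `outer_weights`, `residuals` ([residual_report()] of the ensemble).
#' @export
nested_cv_evaluate <- function(data, specs = learner_library(),
                               v_outer = 10, v_inner = 10, seed = 1,
                               control = sl_control()) {
  u <- outcome_vector(data)
  n <- nrow(data)
  outer <- assign_folds(n, v_outer, substream(seed, "outer-folds"))

  ids <- c(specs$id, "super_learner")
  preds <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  outer_weights <- list()

  for (fold in sort(unique(outer))) {
    tr <- which(outer != fold)
    va <- which(outer == fold)
    slfit <- fit_super_learner(
      subset_cohort(data, tr), specs,
      v = v_inner, seed = substream(seed, "outer", fold), control = control
    )
    p <- predict(slfit, subset_cohort(data, va), learners = TRUE)
    preds[va, colnames(p)] <- p
    preds[va, "super_learner"] <- as.numeric(p %*% slfit$alpha)
    outer_weights[[as.character(fold)]] <- slfit$alpha
  }

  r2 <- apply(preds, 2, cv_r2, u = u)
  mse <- apply(preds, 2, cv_mse, u = u)
  metrics <- tibble(
    learner = ids,
    cv_mse = as.numeric(mse),
    cv_r2 = as.numeric(r2),
    rel_efficiency = relative_efficiency(as.numeric(r2), r2[["super_learner"]])
  )

  structure(
    list(
      metrics = metrics,
      predictions = dplyr::bind_cols(
        tibble(id = seq_len(n), fold = as.integer(outer), observed = u),
        as_tibble(preds)
      ),
      outer_weights = outer_weights,
      residuals = residual_report(u, preds[, "super_learner"]),
      v_outer = v_outer, v_inner = v_inner, seed = seed,
      n = n, k = nrow(specs)
    ),
    class = "sl_evaluation"
  )
}

#' @export
print.sl_evaluation <- function(x, ...) {
  cat(sprintf("<sl_evaluation> nested %d x %d CV, n = %d, K = %d\n",
              x$v_outer, x$v_inner, x$n, x$k))
  m <- x$metrics
  m$cv_r2 <- sprintf("%5.1f%%", 100 * m$cv_r2)
  m$rel_efficiency <- sprintf("%5.1f%%", 100 * m$rel_efficiency)
  print(as.data.frame(m), row.names = FALSE)
  invisible(x)
}

#' @method tidy sl_evaluation
#' @export
tidy.sl_evaluation <- function(x, ...) x$metrics

#' @method glance sl_evaluation
#' @export
glance.sl_evaluation <- function(x, ...) {
  sl <- x$metrics[x$metrics$learner == "super_learner", ]
  tibble(
    n = x$n, k = x$k, v_outer = x$v_outer, v_inner = x$v_inner,
    cv_mse = sl$cv_mse, cv_r2 = sl$cv_r2,
    n_extreme_residuals = attr(x$residuals, "summary")$n_extreme,
    seed = x$seed
  )
}

#' Falsification test with an independent simulated outcome
#'
#' Replaces the unprofitability outcome with a Gaussian variable drawn with
#' the empirical mean and standard deviation of the real outcome but
#' independently of every predictor, then reruns the full nested
#' cross-validation. Any systematic signal found on this outcome indicates
#' leakage in the pipeline; a correct implementation yields a CV R-squared
#' of approximately zero (0.0% to one decimal).
#'
#' @inheritParams nested_cv_evaluate
#' @return The ensemble's nested CV R-squared (fraction, typically within
#'   noise of 0) with the full `sl_evaluation` attached as attribute
#'   `"evaluation"`.
#' @export
falsification_test <- function(data, specs = learner_library(),
                               v_outer = 10, v_inner = 10, seed = 1,
                               control = sl_control()) {
  u <- outcome_vector(data)
  if (sd(u) == 0) abort("`unprofit` is constant; falsification scale undefined.")
  sim <- withr::with_seed(
    substream(seed, "falsify"),
    rnorm(length(u), mean(u), sd(u))
  )
  data$unprofit <- sim
  ev <- nested_cv_evaluate(data, specs, v_outer = v_outer, v_inner = v_inner,
                           seed = seed, control = control)
  r2 <- ev$metrics$cv_r2[ev$metrics$learner == "super_learner"]
  attr(r2, "evaluation") <- ev
  r2
}
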