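#' Capped lasso variable screener with forced inclusion
#'
#' Defines the third variable set of the learner library: a lasso
#' regularization path is fit on the full predictor pool, the penalty is
#' walked from its largest value (empty active set) downward, and the
#' largest active set containing at most `cap` variables is returned. When
#' the active set jumps from `<= cap` straight past the cap between
#' adjacent path knots (simultaneous entrants), the set at the larger
#' penalty is kept — the tied entrants are excluded. The data-selected set
#' is then augmented with the forced class ids (HIV antivirals and MS
#' biologics by default) if not already present, reflecting the very high
#' cost of those therapies. The returned set always comes from a single
#' penalty value; no mixing across the path.
#'
#' The screener is deterministic: no randomness is involved (the penalty is
#' chosen by the cap rule, not by cross-validation). An intercept is always
#' fit and never counts against the cap. Binary predictors are not
#' standardized before penalization (they share a common scale).
#'
#' @param x Numeric predictor matrix with column names.
#' @param u Numeric outcome ($).
#' @param cap Maximum data-selected variables (default 10; `>= 0`).
#' @param forced Character vector of column ids always added (may be empty).
#' @param control An [sl_control()] (supplies the path resolution).
#' @return Object of class `variable_screen`: list with `ids` (final set),
#'   `data_selected` (pre-augmentation), `forced_added`, `lambda` (the
#'   penalty used, `NA` if nothing was selected), `cap`.
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(600, 1, 0.3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' u <- 1000 * x[, 1] + rnorm(200)
#' screen_variables(x, u, cap = 1)$data_selected  # "a"
#' @export
screen_variables <- function(x, u, cap = 10, forced = character(),
                             control = sl_control()) {
  x <- as.matrix(x)
  cap <- assert_scalar_count(cap, "cap", min = 0L)
  forced <- unique(as.character(forced))
  if (!all(forced %in% colnames(x))) {
    abort(sprintf("Forced ids not in `x`: %s",
                  paste(setdiff(forced, colnames(x)), collapse = ", ")))
  }
  if (cap == 0L && length(forced) == 0L) {
    warn("cap = 0 with no forced variables: returning an empty set.")
  }

  mu <- colMeans(x)
  varying <- colnames(x)[colMeans(x^2) - mu^2 > 0]
  selected <- character()
  lambda <- NA_real_

  if (cap > 0L && length(varying) >= 2L && stats::sd(u) > 0) {
    path <- glmnet::glmnet(
      Matrix::Matrix(x[, varying, drop = FALSE], sparse = TRUE), u,
      alpha = 1, standardize = FALSE, nlambda = control$screen_nlambda
    )
    df <- path$df
    over <- which(df > cap)
    knots <- if (length(over) > 0) seq_len(min(over) - 1L) else seq_along(df)
    if (length(knots) > 0 && any(df[knots] > 0)) {
      best <- max(knots[df[knots] == max(df[knots])])  # smallest such lambda
      lambda <- path$lambda[best]
      beta <- path$beta[, best]
      selected <- names(beta)[abs(beta) > 0]
    }
  } else if (cap > 0L && length(varying) == 1L && stats::sd(u) > 0) {
    # Single varying column: keep it if marginally associated at all.
    if (abs(stats::cor(x[, varying], u)) > 0) selected <- varying
  }

  structure(
    list(
      name = "screened",
      ids = union(selected, forced),
      data_selected = selected,
      forced_added = setdiff(forced, selected),
      lambda = lambda,
      cap = cap
    ),
    class = "variable_screen"
  )
}

#' Screen variables inside a cross-validation fold
#'
#' Applies [screen_variables()] to the training rows of a fold only, so
#' validation outcomes can never influence the selection.
#'
#' @param x,u Full-data predictors and outcome.
#' @param training_rows Integer indices of the fold's training rows.
#' @inheritParams screen_variables
#' @export
screen_within_fold <- function(x, u, training_rows, cap = 10,
                               forced = character(), control = sl_control()) {
  x <- as.matrix(x)
  screen_variables(x[training_rows, , drop = FALSE], u[training_rows],
                   cap = cap, forced = forced, control = control)
}

#' @export
print.variable_screen <- function(x, ...) {
  cat(sprintf(
    "<variable_screen> %d data-selected (cap %d, lambda %s) + %d forced\n",
    length(x$data_selected), x$cap,
    ifelse(is.na(x$lambda), "NA", signif(x$lambda, 4)),
    length(x$forced_added)
  ))
  cat(" ", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}
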