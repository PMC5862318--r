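#' Control parameters for learners and the ensemble
#'
#' Bundles the tunable settings of the base algorithms and the ensemble
#' machinery. Defaults are the package's documented choices where the
#' method description leaves them open.
#'
#' @param internal_nfolds Folds for the internal cross-validation that picks
#'   the lasso/ridge penalty (squared-error criterion, minimum-risk lambda,
#'   not 1-SE). Default 10.
#' @param nlambda Length of the internal lasso/ridge penalty grid.
#' @param nnet_size Hidden units of the neural network (default 2, one
#'   hidden layer).
#' @param nnet_decay Weight decay of the neural network (default 0.1).
#' @param nnet_maxit Maximum BFGS iterations for the neural network
#'   (default 40). Inputs are binary and are not standardized; the outcome
#'   is centered and scaled internally for optimizer stability and
#'   back-transformed.
#' @param tree_cp,tree_minsplit Complexity threshold and minimum node size
#'   of the ANOVA regression tree (rpart defaults 0.01 / 20); the tree is
#'   used unpruned at `tree_cp`, so rpart's internal cross-validation and
#'   surrogate-split machinery are disabled.
#' @param screen_cap Maximum number of data-selected variables the lasso
#'   screener may return before forced augmentation (default 10).
#' @param screen_nlambda Knots of the screener's lasso path (default 100,
#'   logarithmic from the smallest empty-set lambda downward).
#' @return A list of class `sl_control`.
#' @export
sl_control <- function(internal_nfolds = 10,
                       nlambda = 50,
                       nnet_size = 2,
                       nnet_decay = 0.1,
                       nnet_maxit = 40,
                       tree_cp = 0.01,
                       tree_minsplit = 20,
                       screen_cap = 10,
                       screen_nlambda = 100) {
  structure(
    list(
      internal_nfolds = assert_scalar_count(internal_nfolds, "internal_nfolds", 2L),
      nlambda = assert_scalar_count(nlambda, "nlambda", 5L),
      nnet_size = assert_scalar_count(nnet_size, "nnet_size", 1L),
      nnet_decay = nnet_decay,
      nnet_maxit = assert_scalar_count(nnet_maxit, "nnet_maxit", 1L),
      tree_cp = tree_cp,
      tree_minsplit = assert_scalar_count(tree_minsplit, "tree_minsplit", 1L),
      screen_cap = assert_scalar_count(screen_cap, "screen_cap", 0L),
      screen_nlambda = assert_scalar_count(screen_nlambda, "screen_nlambda", 10L)
    ),
    class = "sl_control"
  )
}

set_suffix <- c(full = "f", groups = "g", screened = "l")

#' The candidate learner library
#'
#' Crosses the five base algorithms — a two-hidden-unit neural network
#' (`nnet`), lasso (`lasso`) and ridge (`ridge`) regression with the penalty
#' chosen by internal cross-validation, an ANOVA-splitting regression tree
#' (`tree`), and a main-terms linear regression (`glm`) — with the three
#' variable sets (`full`, `groups`, `screened`). Learner ids carry the
#' conventional suffixes `.f`, `.g`, `.l` for the three sets, so the default
#' library is the 15 learners `nnet.f`, ..., `glm.l`.
#'
#' @param algorithms Subset of `c("nnet", "lasso", "ridge", "tree", "glm")`.
#' @param sets Subset of `c("full", "groups", "screened")`.
#' @return A tibble with columns `id`, `algorithm`, `variable_set`.
#' @examples
#' nrow(learner_library())  # 15
#' @export
learner_library <- function(algorithms = c("nnet", "lasso", "ridge", "tree", "glm"),
                            sets = c("full", "groups", "screened")) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  sets <- match.arg(sets, c("full", "groups", "screened"), several.ok = TRUE)
  grid <- tidyr::expand_grid(algorithm = algorithms, variable_set = sets)
  dplyr::mutate(grid,
    id = paste0(.data$algorithm, ".", set_suffix[.data$variable_set]),
    .before = 1L
  )
}

as_learner_spec <- function(spec) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  if (is.null(spec$algorithm)) abort("Learner spec needs an `algorithm` field.")
  if (is.null(spec$id)) {
    spec$id <- paste0(spec$algorithm, ".", set_suffix[[spec$variable_set %||% "full"]])
  }
  spec
}

pad_column <- function(n) {
  Matrix::Matrix(0, n, 1, dimnames = list(NULL, ".pad"), sparse = TRUE)
}

mean_fit <- function(u, reason) {
  list(kind = "mean", mean = mean(u), reason = reason)
}

#' Fit one candidate learner
#'
#' Uniform fit interface over the five base algorithms. All fits are
#' deterministic given `(spec, x, u, seed)`: the seed drives the neural
#' net's weight initialization and the internal cross-validation fold draw
#' of the penalized regressions. A constant outcome (or any fitting
#' failure) degrades to a mean-predicting fit with a warning rather than an
#' error.
#'
#' @param spec One row of [learner_library()] (or an equivalent list).
#' @param x Numeric predictor matrix with column names (binary indicators).
#' @param u Numeric outcome vector ($ unprofitability), `length(u) == nrow(x)`.
#' @param seed Integer seed for this fit.
#' @param control An [sl_control()] list.
#' @return An object of class `fitted_learner` holding the opaque fitted
#'   state, the spec and the training column ids.
#' @export
fit_learner <- function(spec, x, u, seed = 1, control = sl_control()) {
  spec <- as_learner_spec(spec)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(u)) abort("`x` and `u` must agree in length.")
  if (length(u) < control$internal_nfolds &&
      spec$algorithm %in% c("lasso", "ridge")) {
    abort("Fewer rows than internal cross-validation folds.")
  }

  fit <- if (ncol(x) == 0L || stats::sd(u) == 0) {
    warn(sprintf("[%s] degenerate input (constant outcome or no predictors): using mean fit.", spec$id))
    mean_fit(u, "degenerate input")
  } else {
    tryCatch(
      switch(spec$algorithm,
        glm = fit_linear(x, u),
        lasso = fit_glmnet(x, u, alpha = 1, seed, control),
        ridge = fit_glmnet(x, u, alpha = 0, seed, control),
        tree = fit_tree(x, u, control),
        nnet = fit_nnet(x, u, seed, control),
        abort(sprintf("Unknown algorithm `%s`.", spec$algorithm))
      ),
      error = function(e) {
        warn(sprintf("[%s] fit failed (%s): using mean fit.", spec$id,
                     conditionMessage(e)))
        mean_fit(u, conditionMessage(e))
      }
    )
  }

  structure(
    list(spec = spec, columns = colnames(x), fit = fit),
    class = "fitted_learner"
  )
}

fit_linear <- function(x, u) {
  qrx <- lm.fit(cbind(`(Intercept)` = 1, x), u)
  beta <- qrx$coefficients
  beta[is.na(beta)] <- 0  # aliased (collinear) columns contribute nothing
  list(kind = "linear", beta = beta)
}

fit_glmnet <- function(x, u, alpha, seed, control) {
  xs <- Matrix::Matrix(x, sparse = TRUE)
  pad <- ncol(x) < 2L
  if (pad) xs <- cbind(xs, pad_column(nrow(xs)))
  cv <- withr::with_seed(seed, glmnet::cv.glmnet(
    xs, u,
    alpha = alpha, nfolds = control$internal_nfolds,
    standardize = FALSE, nlambda = control$nlambda
  ))
  list(kind = "glmnet", cv = cv, lambda = cv$lambda.min, pad = pad)
}

fit_tree <- function(x, u, control) {
  df <- data.frame(.u = u, x, check.names = FALSE)
  fit <- rpart::rpart(
    .u ~ ., data = df, method = "anova",
    control = rpart::rpart.control(
      cp = control$tree_cp, minsplit = control$tree_minsplit,
      xval = 0, maxsurrogate = 0, maxcompete = 0
    )
  )
  list(kind = "tree", tree = fit)
}

fit_nnet <- function(x, u, seed, control) {
  m <- mean(u)
  s <- stats::sd(u)
  fit <- withr::with_seed(seed, nnet::nnet(
    x, (u - m) / s,
    size = control$nnet_size, linout = TRUE,
    decay = control$nnet_decay, maxit = control$nnet_maxit,
    trace = FALSE, MaxNWts = 100000
  ))
  list(kind = "nnet", net = fit, center = m, scale = s)
}

#' Predict from a fitted learner
#'
#' @param object A `fitted_learner`.
#' @param newdata Matrix or data frame containing exactly the training
#'   columns (any order).
#' @param ... Unused.
#' @return Numeric vector of $ predictions, one per row.
#' @export
predict.fitted_learner <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  missing <- setdiff(object$columns, colnames(x))
  extra_ok <- all(object$columns %in% colnames(x))
  if (length(missing) > 0 || !extra_ok) {
    abort(sprintf(
      "Prediction columns do not match training columns; missing: %s",
      paste(missing, collapse = ", ")
    ))
  }
  x <- x[, object$columns, drop = FALSE]
  fit <- object$fit
  out <- switch(fit$kind,
    mean = rep(fit$mean, nrow(x)),
    linear = as.numeric(cbind(1, x) %*% fit$beta),
    glmnet = {
      xs <- Matrix::Matrix(x, sparse = TRUE)
      if (fit$pad) xs <- cbind(xs, pad_column(nrow(xs)))
      as.numeric(predict(fit$cv, newx = xs, s = "lambda.min"))
    },
    tree = as.numeric(predict(fit$tree, newdata = as.data.frame(x))),
    nnet = as.numeric(predict(fit$net, x)) * fit$scale + fit$center,
    abort("Corrupt fitted_learner.")
  )
  if (!all(is.finite(out))) abort("Non-finite predictions produced.")
  out
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat(sprintf("<fitted_learner> %s (%s) on %d columns\n",
              x$spec$id, x$fit$kind, length(x$columns)))
  invisible(x)
}
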