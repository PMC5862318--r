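# Shared fixtures, built in code at test time.

small_vocab <- function(n_classes = 12, n_groups = 3, n_generic = 2,
                        n_maintenance = 2) {
  generate_vocabulary(n_classes, n_groups, n_generic, n_maintenance)
}

# A small cohort with payments derived, ready for the ensemble.
small_cohort <- function(n = 400, seed = 11, vocab = small_vocab(), ...) {
  cfg <- cohort_config(vocab, n = n, seed = seed, ...)
  add_plan_payments(generate_cohort(vocab, cfg))
}

# Cheap learner pair for structural / leakage tests.
fast_specs <- function() {
  learner_library(algorithms = c("glm", "tree"), sets = c("groups", "screened"))
}

# Random binary design with named columns.
binary_design <- function(n, p, prob = 0.3, seed = 1, prefix = "cls_") {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * p, 1, prob), n, p)
    colnames(x) <- sprintf("%s%03d", prefix, seq_len(p))
    storage.mode(x) <- "double"
    x
  })
}

# Dense grid search over the 2- or 3-simplex: the independent oracle for
# convex ensemble-weight estimation.
grid_search_simplex <- function(u, z, step = 0.01) {
  k <- ncol(z)
  stopifnot(k %in% 2:3)
  grid <- seq(0, 1, by = step)
  best <- NULL
  best_obj <- Inf
  for (a1 in grid) {
    alphas <- if (k == 2) {
      list(c(a1, 1 - a1))
    } else {
      lapply(seq(0, 1 - a1, by = step), function(a2) c(a1, a2, 1 - a1 - a2))
    }
    for (a in alphas) {
      obj <- mean((u - as.numeric(z %*% a))^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- a
      }
    }
  }
  list(alpha = best, objective = best_obj)
}

# Orthonormal design whose columns are also orthogonal to the intercept,
# for closed-form penalized-regression oracles.
orthonormal_design <- function(n, p, seed = 5) {
  withr::with_seed(seed, {
    m <- cbind(1, matrix(rnorm(n * (p + 1)), n))
    q <- qr.Q(qr(m))[, 2:(p + 1), drop = FALSE]
    colnames(q) <- paste0("v", seq_len(p))
    q
  })
}
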