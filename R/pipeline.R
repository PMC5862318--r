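#' Configuration of a full pipeline run
#'
#' Snapshot of everything a run needs: cohort generator settings, learner
#' library, fold counts, screener settings, the run seed and the output
#' directory. A config plus its seed reproduces a run bit-for-bit.
#'
#' @param out_dir Output directory (created if absent).
#' @param n Cohort size.
#' @param seed Integer run seed (single source of all randomness; stages
#'   use named substreams).
#' @param vocab_args List of arguments to [generate_vocabulary()].
#' @param cohort_args List of extra arguments to [cohort_config()].
#' @param specs Learner library tibble (default all 15 learners).
#' @param v_inner,v_outer Inner / outer fold counts.
#' @param control An [sl_control()].
#' @param falsify If `TRUE`, the metrics report additionally contains the
#'   falsification CV R-squared.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, n = 2000, seed = 1,
                            vocab_args = list(), cohort_args = list(),
                            specs = learner_library(),
                            v_inner = 10, v_outer = 10,
                            control = sl_control(), falsify = FALSE) {
  structure(
    list(
      out_dir = out_dir, n = n, seed = seed,
      vocab_args = vocab_args, cohort_args = cohort_args,
      specs = specs, v_inner = v_inner, v_outer = v_outer,
      control = control, falsify = isTRUE(falsify)
    ),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' generate -> derive -> ensemble -> evaluate, with every artifact written
#' to `config$out_dir`: the cohort CSV, the payment-augmented CSV, the
#' fitted ensemble JSON (weights, learner ids, screened sets, config hash),
#' the metrics JSON, the screened-variable audit JSON and a timing log. A
#' failure in any stage aborts with a message naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the artifact paths and the in-memory
#'   `super_learner` and `sl_evaluation` objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  stamp <- function(stage, t0) {
    line <- sprintf("%s: %.2fs", stage, as.numeric(Sys.time()) - t0)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    stamp(name, t0)
    out
  }
  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    payments = file.path(config$out_dir, "cohort_payments.csv"),
    vocabulary = file.path(config$out_dir, "vocabulary.json"),
    fit = file.path(config$out_dir, "superlearner.json"),
    metrics = file.path(config$out_dir, "metrics.json"),
    audit = file.path(config$out_dir, "screen_audit.json"),
    log = file.path(config$out_dir, "run_log.txt")
  )

  vocab <- stage("generate_vocabulary",
                 do.call(generate_vocabulary, config$vocab_args))
  cohort <- stage("generate_cohort", {
    cc <- do.call(cohort_config, c(
      list(vocab = vocab, n = config$n, seed = config$seed),
      config$cohort_args
    ))
    co <- generate_cohort(vocab, cc)
    write_cohort(co, paths$cohort)
    write_vocabulary(vocab, paths$vocabulary)
    co
  })
  cohort <- stage("derive_payments", {
    co <- add_plan_payments(cohort)
    write_cohort(co, paths$payments)
    co
  })
  slfit <- stage("fit_super_learner", {
    fit <- fit_super_learner(cohort, config$specs, v = config$v_inner,
                             seed = config$seed, control = config$control)
    write_report(fit, paths$fit)
    fit
  })
  ev <- stage("nested_cv_evaluate", {
    nested_cv_evaluate(cohort, config$specs, v_outer = config$v_outer,
                       v_inner = config$v_inner, seed = config$seed,
                       control = config$control)
  })
  fals <- NULL
  if (config$falsify) {
    fals <- stage("falsification_test", {
      as.numeric(falsification_test(cohort, config$specs,
                                    v_outer = config$v_outer,
                                    v_inner = config$v_inner,
                                    seed = config$seed,
                                    control = config$control))
    })
  }
  stage("write_reports", {
    write_report(ev, paths$metrics, falsification_r2 = fals)
    audit <- list(
      full_data = screen_audit_entry(slfit$screened_full),
      weight_estimation_folds = lapply(slfit$cv$screened, screen_audit_entry)
    )
    jsonlite::write_json(audit, paths$audit, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  writeLines(c(sprintf("config_hash: %s", config_hash(config)), log_lines),
             paths$log)
  invisible(list(paths = paths, fit = slfit, evaluation = ev,
                 falsification_r2 = fals, cohort = cohort))
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

screen_audit_entry <- function(scr) {
  if (is.null(scr)) return(NULL)
  list(
    lambda = scr$lambda,
    data_selected = as.list(scr$data_selected),
    forced_added = as.list(scr$forced_added),
    ids = as.list(scr$ids)
  )
}

#' Write / read a cohort CSV
#'
#' The cohort is stored as a plain CSV with a header row: `id`, the
#' numeric columns (`cost`, `risk_score`, optionally `drug_cost`, payment
#' columns, demographics), and the binary indicator columns. `read_cohort`
#' validates the contract and names the offending rows/columns: costs must
#' be non-negative, risk scores positive, indicators exactly 0/1, no
#' missing values.
#'
#' @param data Cohort tibble.
#' @param path File path.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: the cohort
#'   tibble (with the vocabulary attached when `vocabulary` is supplied).
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_cohort
#' @param vocabulary Optional `drug_vocabulary` (or path to a vocabulary
#'   JSON) to attach to the result.
#' @export
read_cohort <- function(path, vocabulary = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "cost", "risk_score")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Cohort file lacks required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyNA(data)) {
    abort(sprintf("Missing values in rows: %s",
                  paste(head(which(rowSums(is.na(data)) > 0), 5), collapse = ", ")))
  }
  bad_cost <- which(data$cost < 0)
  if (length(bad_cost) > 0) {
    abort(sprintf("Negative cost at row(s): %s",
                  paste(head(bad_cost, 5), collapse = ", ")))
  }
  bad_risk <- which(data$risk_score <= 0)
  if (length(bad_risk) > 0) {
    abort(sprintf("Non-positive risk score at row(s): %s",
                  paste(head(bad_risk, 5), collapse = ", ")))
  }
  for (col in indicator_columns(data)) {
    bad <- which(!(data[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("Indicator `%s` is not binary at row(s): %s", col,
                    paste(head(bad, 5), collapse = ", ")))
    }
    data[[col]] <- as.integer(data[[col]])
  }
  if (!is.null(vocabulary)) {
    if (is.character(vocabulary)) vocabulary <- read_vocabulary(vocabulary)
    attr(data, "vocabulary") <- vocabulary
  }
  data
}

#' Write / read a vocabulary as JSON
#'
#' @param vocab A `drug_vocabulary`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(
      classes = vocab$classes,
      group_ids = vocab$group_ids,
      generic_ids = vocab$generic_ids,
      maintenance_ids = vocab$maintenance_ids,
      forced_ids = vocab$forced_ids
    ),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      classes = as_tibble(raw$classes),
      group_ids = raw$group_ids,
      generic_ids = raw$generic_ids,
      maintenance_ids = raw$maintenance_ids,
      forced_ids = raw$forced_ids
    ),
    class = "drug_vocabulary"
  )
}

#' Serialize a result object to JSON
#'
#' Writes a `super_learner` fit (weights, learner ids, screened sets) or an
#' `sl_evaluation` (metric table, residual summary, per-fold weights) as a
#' JSON report.
#'
#' @param report A `super_learner` or `sl_evaluation`.
#' @param path File path.
#' @param falsification_r2 Optional falsification CV R-squared to embed in
#'   an evaluation report.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, falsification_r2 = NULL) {
  payload <- if (inherits(report, "super_learner")) {
    list(
      type = "super_learner",
      weights = as.list(report$alpha),
      learners = tidy(report),
      v = report$v, n = report$n, seed = report$seed,
      cv_objective = report$weights$objective,
      screened_full = screen_audit_entry(report$screened_full)
    )
  } else if (inherits(report, "sl_evaluation")) {
    out <- list(
      type = "sl_evaluation",
      metrics = report$metrics,
      v_outer = report$v_outer, v_inner = report$v_inner,
      n = report$n, k = report$k, seed = report$seed,
      residual_summary = attr(report$residuals, "summary"),
      outer_weights = lapply(report$outer_weights, as.list)
    )
    if (!is.null(falsification_r2)) out$falsification_cv_r2 <- falsification_r2
    out
  } else {
    abort("`report` must be a super_learner or sl_evaluation object.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
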