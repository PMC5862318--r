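#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the claims-cohort simulator in one validated list.
#' Per-class parameters (prevalence, additive expected-cost effect in $/year,
#' and the fraction of that effect captured by the diagnosis-based risk
#' score) are drawn once, reproducibly, from `seed` unless supplied
#' explicitly. The two forced high-cost classes (HIV antivirals, MS
#' biologics) get low prevalence and large cost effects.
#'
#' The cost model is two-part and heavy tailed: a Bernoulli indicator of any
#' non-drug spending times a lognormal severity, plus (for drug users) a
#' lognormal drug spend and a lognormal medical load tied to the enrollee's
#' therapeutic classes, plus a rare Pareto outlier component independent of
#' all predictors. `risk_capture[c]` attenuates class `c`'s contribution to
#' the risk score: classes with capture < 1 carry residual unprofitability
#' signal, the phenomenon the downstream prediction problem targets.
#'
#' @param vocab A [generate_vocabulary()] object.
#' @param n Number of enrollees (>= 2).
#' @param seed Integer seed governing all randomness (per-stage substreams
#'   are derived from it deterministically).
#' @param zero_drug_spend_frac Probability an enrollee has no drug spending
#'   at all (all indicators zero). Default 0.3.
#' @param class_prevalences Named vector of population prevalences per class;
#'   default drawn from a right-skewed Beta so a typical user carries a
#'   handful of classes.
#' @param class_cost_effects Named vector of additive expected-cost effects
#'   ($/year) per class; default lognormal around a few hundred dollars,
#'   with $25,000 / $30,000 for the forced HIV / MS classes.
#' @param risk_capture Named vector in `[0, 1]`: fraction of each class's
#'   cost effect reflected in the risk score (default Beta(8, 2), mean 0.8).
#' @param group_assoc Within-group indicator association in `[0, 1]`: the
#'   probability a class indicator copies its group's shared latent uniform
#'   rather than an independent one (Gaussian-free copula; marginal
#'   prevalences are exact). Default 0.3.
#' @param baseline_mean Mean non-drug annual spending in $ (default 3000).
#' @param baseline_zero_frac Probability of zero non-drug spending
#'   (default 0.15).
#' @param baseline_sdlog Lognormal sdlog of non-drug severity (default 1.4).
#' @param drug_base_mean Mean annual drug spend of a drug user before class
#'   effects, $ (default 600).
#' @param drug_sdlog,load_sdlog Lognormal sdlog of the multiplicative noise
#'   on drug spend and on the class-driven medical load.
#' @param drug_frac_of_effect Fraction of each class cost effect booked as
#'   drug (vs medical) spending; affects only the drug-spend summary column.
#' @param outlier_rate,outlier_scale,outlier_shape Rare catastrophic-cost
#'   mixture: with probability `outlier_rate` a Pareto(`outlier_scale`,
#'   `outlier_shape`) amount is added to cost, independent of all indicators.
#' @param risk_noise_sd Relative sd of multiplicative Gaussian noise on the
#'   risk score (default 0.25); set 0 for a noise-free score.
#' @param risk_floor Lower bound applied to the raw risk index before
#'   mean-normalization (default 0.05).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(vocab,
                          n = 10000,
                          seed = 1,
                          zero_drug_spend_frac = 0.3,
                          class_prevalences = NULL,
                          class_cost_effects = NULL,
                          risk_capture = NULL,
                          group_assoc = 0.3,
                          baseline_mean = 3000,
                          baseline_zero_frac = 0.15,
                          baseline_sdlog = 1.4,
                          drug_base_mean = 600,
                          drug_sdlog = 0.8,
                          load_sdlog = 0.8,
                          drug_frac_of_effect = 0.3,
                          outlier_rate = 2e-4,
                          outlier_scale = 5e5,
                          outlier_shape = 1.5,
                          risk_noise_sd = 0.25,
                          risk_floor = 0.05) {
  stopifnot(inherits(vocab, "drug_vocabulary"))
  n <- assert_scalar_count(n, "n", min = 2L)
  seed <- assert_scalar_count(abs(seed), "seed", min = 0L)
  assert_prob(zero_drug_spend_frac, "zero_drug_spend_frac")
  assert_prob(group_assoc, "group_assoc")
  assert_prob(baseline_zero_frac, "baseline_zero_frac")
  assert_prob(drug_frac_of_effect, "drug_frac_of_effect")
  assert_prob(outlier_rate, "outlier_rate")
  stopifnot(
    baseline_mean >= 0, drug_base_mean >= 0, outlier_scale > 0,
    outlier_shape > 1, risk_noise_sd >= 0, risk_floor > 0
  )

  ids <- vocab$classes$class_id
  p_user <- 1 - zero_drug_spend_frac

  defaults <- withr::with_seed(substream(seed, "class-params"), {
    prev <- stats::rbeta(length(ids), 0.4, 30)
    eff <- rlnorm(length(ids), log(150), 1.2)
    cap <- stats::rbeta(length(ids), 8, 2)
    list(prev = prev, eff = pmin(eff, 2e4), cap = cap)
  })

  if (is.null(class_prevalences)) {
    class_prevalences <- stats::setNames(defaults$prev, ids)
    class_prevalences[vocab$forced_ids] <-
      rep_len(c(0.004, 0.002), length(vocab$forced_ids))
  }
  if (is.null(class_cost_effects)) {
    class_cost_effects <- stats::setNames(defaults$eff, ids)
    class_cost_effects[vocab$forced_ids] <-
      rep_len(c(25000, 30000), length(vocab$forced_ids))
  }
  if (is.null(risk_capture)) {
    risk_capture <- stats::setNames(defaults$cap, ids)
  }

  for (nm in c("class_prevalences", "class_cost_effects", "risk_capture")) {
    v <- get(nm)
    if (is.null(names(v)) || !setequal(names(v), ids)) {
      abort(sprintf("`%s` must be named by every class id of the vocabulary.", nm))
    }
  }
  assert_prob(class_prevalences, "class_prevalences")
  assert_prob(risk_capture, "risk_capture")
  if (any(class_cost_effects < 0)) abort("`class_cost_effects` must be >= 0.")
  # Conditional-on-user prevalence must stay a probability.
  if (p_user > 0 && any(class_prevalences / p_user > 0.995)) {
    abort("Some `class_prevalences` exceed 0.995 * (1 - zero_drug_spend_frac).")
  }

  structure(
    list(
      n = n, seed = seed,
      zero_drug_spend_frac = zero_drug_spend_frac,
      class_prevalences = class_prevalences[ids],
      class_cost_effects = class_cost_effects[ids],
      risk_capture = risk_capture[ids],
      group_assoc = group_assoc,
      baseline_mean = baseline_mean,
      baseline_zero_frac = baseline_zero_frac,
      baseline_sdlog = baseline_sdlog,
      drug_base_mean = drug_base_mean,
      drug_sdlog = drug_sdlog,
      load_sdlog = load_sdlog,
      drug_frac_of_effect = drug_frac_of_effect,
      outlier_rate = outlier_rate,
      outlier_scale = outlier_scale,
      outlier_shape = outlier_shape,
      risk_noise_sd = risk_noise_sd,
      risk_floor = risk_floor
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n = %d, seed = %d, zero-drug-spend %.0f%%, %d classes\n",
    x$n, x$seed, 100 * x$zero_drug_spend_frac, length(x$class_prevalences)
  ))
  invisible(x)
}

# Expected cost of enrollee i given user status and class indicators:
#   E[C | user, X] = baseline_mean + outlier_mean
#                    + user * drug_base_mean + sum_c delta_c X_c
# The generator enforces this exactly (all noise is mean-one multiplicative
# or additive mean-zero-adjusted), which is what makes the parameter-recovery
# and full-capture-neutrality properties hold analytically.
outlier_mean <- function(config) {
  config$outlier_rate * config$outlier_shape * config$outlier_scale /
    (config$outlier_shape - 1)
}

#' Generate a synthetic enrollee cohort
#'
#' Simulates one enrollee per row: annual total cost `cost` ($), drug
#' spending `drug_cost` ($, zero for the configured fraction of non-users),
#' a positive mean-one diagnosis-based `risk_score`, summary-only
#' demographics (`age`, `female`), and the full binary indicator hierarchy
#' (class `cls_*`, group `grp_*`, generic `gen_*`, maintenance `mnt_*`
#' columns). Group, generic and maintenance indicators are exact ORs of
#' their member class indicators.
#'
#' The risk score is a mean-normalized noisy copy of the enrollee's expected
#' cost in which each class effect is attenuated by `risk_capture[c]`; with
#' full capture and no noise, risk adjustment neutralizes every class's
#' selection signal in expectation, and any shortfall in capture leaves
#' residual signal for the prediction pipeline to find. Generation is fully
#' reproducible from `config$seed`.
#'
#' @param vocab A `drug_vocabulary`.
#' @param config A [cohort_config()] built from the same vocabulary.
#' @return A tibble with one row per enrollee and the vocabulary attached as
#'   attribute `"vocabulary"`.
#' @examples
#' vocab <- generate_vocabulary(n_classes = 12, n_groups = 3)
#' cohort <- generate_cohort(vocab, cohort_config(vocab, n = 500, seed = 42))
#' mean(cohort$drug_cost == 0)  # ~ 0.3
#' @export
generate_cohort <- function(vocab, config) {
  stopifnot(inherits(vocab, "drug_vocabulary"), inherits(config, "cohort_config"))
  n <- config$n
  ids <- vocab$classes$class_id
  if (!setequal(names(config$class_prevalences), ids)) {
    abort("`config` was built for a different vocabulary.")
  }
  seed <- config$seed
  p_user <- 1 - config$zero_drug_spend_frac

  user <- withr::with_seed(
    substream(seed, "user"),
    rbinom(n, 1L, p_user)
  )

  # Class indicators: per-group latent-uniform copula so classes within a
  # therapeutic group co-occur, with exact marginal prevalences.
  X <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  q <- if (p_user > 0) {
    pmin(config$class_prevalences / p_user, 0.995)
  } else {
    stats::setNames(rep(0, length(ids)), ids)
  }
  idx_user <- which(user == 1L)
  nu <- length(idx_user)
  if (nu > 0) {
    withr::with_seed(substream(seed, "copula"), {
      for (g in vocab$group_ids) {
        members <- vocab$classes$class_id[vocab$classes$group_id == g]
        v_g <- runif(nu)
        for (m in members) {
          share <- runif(nu) < config$group_assoc
          u <- ifelse(share, v_g, runif(nu))
          X[idx_user[u < q[[m]]], m] <- 1L
        }
      }
    })
  }

  # Costs.
  load <- as.numeric(X %*% config$class_cost_effects)
  captured <- as.numeric(X %*% (config$risk_capture * config$class_cost_effects))
  costs <- withr::with_seed(substream(seed, "cost"), {
    base_mean_pos <- if (config$baseline_zero_frac < 1) {
      config$baseline_mean / (1 - config$baseline_zero_frac)
    } else 0
    base <- rbinom(n, 1L, 1 - config$baseline_zero_frac) *
      rlnorm(n, log(max(base_mean_pos, 1e-12)) - config$baseline_sdlog^2 / 2,
             config$baseline_sdlog)
    drug <- user * (config$drug_base_mean + config$drug_frac_of_effect * load) *
      rlnorm(n, -config$drug_sdlog^2 / 2, config$drug_sdlog)
    med <- (1 - config$drug_frac_of_effect) * load *
      rlnorm(n, -config$load_sdlog^2 / 2, config$load_sdlog)
    out <- rbinom(n, 1L, config$outlier_rate) *
      config$outlier_scale * runif(n)^(-1 / config$outlier_shape)
    list(base = base, drug = drug, med = med, outlier = out)
  })
  cost <- costs$base + costs$drug + costs$med + costs$outlier

  # Risk score: attenuated expected cost, noisy, floored, mean-normalized.
  m <- config$baseline_mean + outlier_mean(config) +
    user * config$drug_base_mean + captured
  s_raw <- withr::with_seed(
    substream(seed, "risk"),
    pmax(config$risk_floor, m * (1 + config$risk_noise_sd * rnorm(n)))
  )
  risk_score <- s_raw / mean(s_raw)

  demo <- withr::with_seed(substream(seed, "demo"), {
    list(
      age = as.integer(pmin(64, pmax(18, round(rnorm(n, 42, 13))))),
      female = rbinom(n, 1L, 0.49)
    )
  })

  # Aggregate indicators: exact ORs of member classes.
  agg <- function(assignment, all_ids) {
    out <- matrix(0L, n, length(all_ids), dimnames = list(NULL, all_ids))
    for (a in unique(assignment)) {
      members <- ids[assignment == a]
      out[, a] <- as.integer(rowSums(X[, members, drop = FALSE]) > 0)
    }
    out
  }
  G <- agg(vocab$classes$group_id, vocab$group_ids)
  GE <- agg(vocab$classes$generic_id, vocab$generic_ids)
  MN <- agg(vocab$classes$maintenance_id, vocab$maintenance_ids)

  out <- dplyr::bind_cols(
    tibble(
      id = seq_len(n),
      age = demo$age,
      female = demo$female,
      cost = cost,
      drug_cost = costs$drug,
      risk_score = risk_score
    ),
    as_tibble(X), as_tibble(G), as_tibble(GE), as_tibble(MN)
  )
  attr(out, "vocabulary") <- vocab
  attr(out, "cohort_config") <- config
  out
}

#' Retrieve the vocabulary attached to a cohort
#' @param data A cohort tibble from [generate_cohort()] (or a pruned copy).
#' @return The `drug_vocabulary`, or `NULL` if none is attached.
#' @export
cohort_vocabulary <- function(data) attr(data, "vocabulary")

#' Drop indicator variables without positive claims
#'
#' Removes every indicator column with no positive values (no enrollee in
#' the sample uses a drug of that category) and then removes group columns
#' whose surviving membership is a single class, since such a group
#' indicator duplicates its only member. Mirrors the deduplication applied
#' to the analytic claims extract. The attached vocabulary is pruned to
#' match.
#'
#' @param data A cohort tibble.
#' @param vocab Vocabulary describing `data`; defaults to the attached one.
#' @return The pruned cohort tibble (message reports surviving indicator
#'   count; a warning is raised if no indicator survives).
#' @export
drop_empty_variables <- function(data, vocab = cohort_vocabulary(data)) {
  ind <- indicator_columns(data)
  if (length(ind) == 0) {
    warn("No indicator columns present.")
    return(data)
  }
  empty <- ind[purrr::map_lgl(data[ind], ~ all(.x == 0))]
  keep <- setdiff(ind, empty)

  singleton_groups <- character()
  if (!is.null(vocab)) {
    surviving <- vocab$classes[vocab$classes$class_id %in% keep, ]
    counts <- table(surviving$group_id)
    singleton_groups <- intersect(
      names(counts)[counts <= 1L],
      keep[is_group_col(keep)]
    )
    # Groups whose classes all vanished are already in `empty`.
    keep <- setdiff(keep, singleton_groups)

    vocab$classes <- surviving
    vocab$group_ids <- intersect(vocab$group_ids, keep)
    vocab$generic_ids <- intersect(vocab$generic_ids, keep)
    vocab$maintenance_ids <- intersect(vocab$maintenance_ids, keep)
    vocab$forced_ids <- intersect(vocab$forced_ids, keep)
  }

  out <- data[c(setdiff(names(data), ind), keep)]
  if (length(keep) == 0) {
    warn("All indicator columns were empty; returning a table with none.")
  } else {
    inform(sprintf(
      "Dropped %d empty indicator(s) and %d singleton group indicator(s); %d remain.",
      length(empty), length(singleton_groups), length(keep)
    ))
  }
  attr(out, "vocabulary") <- vocab
  attr(out, "cohort_config") <- attr(data, "cohort_config")
  out
}
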