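# Marketplace-style plan payment accounting.
#
# Every enrollee pays the community-rated premium M_i = C-bar (mean market
# cost), receives a risk-adjustment transfer A_i = (S_i / S-bar - 1) * C-bar,
# so revenue R_i = C-bar * S_i / S-bar, profit F_i = R_i - C_i, and
# unprofitability U_i = -F_i = C_i - C-bar * S_i / S-bar. Transfers are
# budget neutral and U has cohort mean exactly zero; both identities are
# algebraic consequences of the formulas and are enforced to numerical
# tolerance throughout.

#' Community-rated premium
#'
#' The premium every plan charges every enrollee: the average annual cost in
#' the market, \eqn{\bar C = n^{-1} \sum_i C_i}.
#'
#' @param costs Numeric vector of annual costs in $, all `>= 0`.
#' @return Scalar premium in $.
#' @export
compute_premium <- function(costs) {
  if (length(costs) == 0) abort("`costs` must be non-empty.")
  if (any(is.na(costs)) || any(costs < 0)) abort("`costs` must be non-negative and complete.")
  mean(costs)
}

#' Risk-adjustment transfers
#'
#' Simplified Marketplace transfer formula:
#' \eqn{A_i = (S_i / \bar S - 1)\,\bar C}. Transfers sum to zero by
#' construction (budget neutrality).
#'
#' @param risk_scores Positive numeric vector of diagnosis-based risk scores.
#' @param premium Scalar premium \eqn{\bar C} in $.
#' @return Numeric vector of signed transfers in $.
#' @export
compute_transfers <- function(risk_scores, premium) {
  if (length(risk_scores) == 0) abort("`risk_scores` must be non-empty.")
  if (any(is.na(risk_scores)) || any(risk_scores <= 0)) {
    abort("All `risk_scores` must be positive.")
  }
  stopifnot(is.numeric(premium), length(premium) == 1L, premium >= 0)
  (risk_scores / mean(risk_scores) - 1) * premium
}

#' Per-enrollee payment components and unprofitability
#'
#' Derives premium, transfer, revenue, profit and unprofitability for each
#' enrollee from costs and risk scores:
#' \eqn{U_i = C_i - \bar C\, S_i / \bar S}, with \eqn{F_i = -U_i}.
#' The cohort mean of \eqn{U_i} is zero by construction.
#'
#' @param costs Annual costs in $, `>= 0`.
#' @param risk_scores Positive risk scores, same length.
#' @return A tibble with columns `premium`, `transfer`, `revenue`, `profit`,
#'   `unprofit` and scalar attributes `mean_cost` and `mean_risk`.
#' @examples
#' compute_unprofitability(c(100, 300), c(1, 1))$unprofit  # -100, 100
#' @export
compute_unprofitability <- function(costs, risk_scores) {
  if (length(costs) != length(risk_scores)) {
    abort("`costs` and `risk_scores` must have equal length.")
  }
  if (length(costs) == 1L) {
    warn("Cohort of a single enrollee: transfers and unprofitability are identically zero.")
  }
  premium <- compute_premium(costs)
  transfer <- compute_transfers(risk_scores, premium)
  revenue <- premium + transfer
  profit <- revenue - costs
  out <- tibble(
    premium = rep(premium, length(costs)),
    transfer = transfer,
    revenue = revenue,
    profit = profit,
    unprofit = -profit
  )
  attr(out, "mean_cost") <- premium
  attr(out, "mean_risk") <- mean(risk_scores)
  out
}

#' Append plan-payment columns to a cohort
#'
#' Tidy wrapper around [compute_unprofitability()]: takes a cohort tibble
#' with `cost` and `risk_score` columns and appends `premium`, `transfer`,
#' `revenue`, `profit` and `unprofit` columns. `unprofit` is the outcome
#' every downstream learner predicts.
#'
#' @param data Cohort tibble with numeric `cost` (>= 0) and positive
#'   `risk_score` columns.
#' @return `data` with the five payment columns appended.
#' @export
add_plan_payments <- function(data) {
  if (!all(c("cost", "risk_score") %in% names(data))) {
    abort("`data` must contain `cost` and `risk_score` columns.")
  }
  pc <- compute_unprofitability(data$cost, data$risk_score)
  out <- dplyr::bind_cols(data, pc)
  attr(out, "vocabulary") <- attr(data, "vocabulary")
  attr(out, "cohort_config") <- attr(data, "cohort_config")
  out
}
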