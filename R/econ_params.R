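#' Economic parameters: utilities, costs, pricing, discounting
#'
#' Base-case defaults follow the published evaluation: state utilities
#' (EQ-5D-derived) of 0.64 post-DFU, 0.61 non-severe DFU, 0.47 severe DFU,
#' 0.34 amputation, 0.47 post-amputation and 0 for death; monthly state costs
#' (2017/18 GBP) of 180.70, 453.83, 972.30, 1106.19 and 311.96; app price
#' 4.99 GBP/month (monthly pricing scenario); 90% compliance; 3.5% annual
#' discount rate for both costs and outcomes; willingness-to-pay 20,000
#' GBP/QALY.
#'
#' @param utilities named numeric, QALY weight per year in each state
#'   (death must be 0).
#' @param monthly_costs named numeric, GBP per monthly cycle in each state.
#' @param app_price_monthly GBP per cycle charged for the app while alive.
#' @param compliance proportion of users compliant with the app, in \[0, 1\].
#' @param discount_outcomes,discount_costs annual discount rates, in
#'   \[0, 0.5).
#' @param wtp willingness-to-pay threshold, GBP per QALY.
#' @return Object of class `dfu_econ`.
#' @export
economic_parameters <- function(utilities = c(post_dfu = 0.64,
                                              nonsevere_dfu = 0.61,
                                              severe_dfu = 0.47,
                                              amputation = 0.34,
                                              post_amputation = 0.47,
                                              death = 0),
                                monthly_costs = c(post_dfu = 180.70,
                                                  nonsevere_dfu = 453.83,
                                                  severe_dfu = 972.30,
                                                  amputation = 1106.19,
                                                  post_amputation = 311.96,
                                                  death = 0),
                                app_price_monthly = 4.99,
                                compliance = 0.90,
                                discount_outcomes = 0.035,
                                discount_costs = 0.035,
                                wtp = 20000) {
  states <- dfu_states()
  utilities <- utilities[states]
  monthly_costs <- monthly_costs[states]
  if (anyNA(utilities) || anyNA(monthly_costs)) {
    stop("utilities and monthly_costs must name all six states: ",
         paste(states, collapse = ", "))
  }
  if (utilities[["death"]] != 0) stop("utility of death must be 0")
  if (any(utilities < 0 | utilities > 1)) stop("utilities must lie in [0, 1]")
  if (any(monthly_costs < 0)) stop("costs must be non-negative")
  if (app_price_monthly < 0) stop("app price must be non-negative")
  if (compliance < 0 || compliance > 1) stop("compliance must lie in [0, 1]")
  for (r in c(discount_outcomes, discount_costs)) {
    if (r < 0 || r >= 0.5) stop("discount rates must lie in [0, 0.5)")
  }
  if (wtp < 0) stop("willingness-to-pay must be non-negative")
  structure(list(utilities = utilities, monthly_costs = monthly_costs,
                 app_price_monthly = app_price_monthly, compliance = compliance,
                 discount_outcomes = discount_outcomes,
                 discount_costs = discount_costs, wtp = wtp),
            class = "dfu_econ")
}

#' App pricing scenarios
#'
#' The three pricing options considered: free (0.00), monthly (4.99) and
#' annual (4.17 GBP per month on average under an annual schedule).
#'
#' @param option one of `"free"`, `"monthly"`, `"annual"`.
#' @return Monthly price in GBP.
#' @export
app_price <- function(option) {
  prices <- c(free = 0.00, monthly = 4.99, annual = 4.17)
  if (!is.character(option) || length(option) != 1 || !option %in% names(prices)) {
    stop("unknown pricing option '", paste(option, collapse = ","),
         "'; valid options: ", paste(names(prices), collapse = ", "))
  }
  prices[[option]]
}

#' Model run configuration
#'
#' The simulated cohort enters at a mean age of 67 years (70% male) in the
#' post-DFU state and is followed over a lifetime horizon: monthly cycles
#' until `max_age_years` or until the surviving fraction falls below
#' `residual_alive_tolerance`.
#'
#' @param baseline_age_years cohort age at entry (years).
#' @param proportion_male cohort proportion male (metadata; transition
#'   probabilities are state-constant, not sex-specific).
#' @param max_age_years horizon cap; must exceed the baseline age.
#' @param residual_alive_tolerance stop once the alive fraction drops below
#'   this value.
#' @param half_cycle_correction logical; average start- and end-of-cycle
#'   occupancy when accumulating outcomes (standard Markov cohort practice).
#' @param discounting `"continuous"` for a per-cycle factor
#'   (1+r)^(-cycle/12), or `"annual_step"` for conventional annual step
#'   discounting (1+r)^(-floor(cycle/12)).
#' @param intervention_rr default relative risk of recurrence used by
#'   strategy evaluation, in (0, 1].
#' @return Object of class `dfu_config`.
#' @export
model_config <- function(baseline_age_years = 67,
                         proportion_male = 0.70,
                         max_age_years = 100,
                         residual_alive_tolerance = 1e-6,
                         half_cycle_correction = TRUE,
                         discounting = c("continuous", "annual_step"),
                         intervention_rr = 1) {
  discounting <- match.arg(discounting)
  if (max_age_years <= baseline_age_years) {
    stop("max_age_years must exceed baseline_age_years")
  }
  if (proportion_male < 0 || proportion_male > 1) {
    stop("proportion_male must lie in [0, 1]")
  }
  if (residual_alive_tolerance < 0 || residual_alive_tolerance >= 1) {
    stop("residual_alive_tolerance must lie in [0, 1)")
  }
  if (intervention_rr <= 0 || intervention_rr > 1) {
    stop("intervention_rr must lie in (0, 1]")
  }
  structure(list(cycle_length_months = 1,
                 baseline_age_years = baseline_age_years,
                 proportion_male = proportion_male,
                 max_age_years = max_age_years,
                 residual_alive_tolerance = residual_alive_tolerance,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 discounting = discounting,
                 intervention_rr = intervention_rr),
            class = "dfu_config")
}
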