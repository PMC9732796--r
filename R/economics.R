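#' Strategy result container
#'
#' @param label text label.
#' @param discounted_qalys,discounted_costs totals from
#'   [accumulate_outcomes()].
#' @return Object of class `dfu_strategy_result`.
#' @export
strategy_result <- function(label, discounted_qalys, discounted_costs) {
  if (discounted_qalys < 0 || discounted_costs < 0) {
    stop("strategy QALYs and costs must be non-negative")
  }
  structure(list(label = label, discounted_qalys = discounted_qalys,
                 discounted_costs = discounted_costs),
            class = "dfu_strategy_result")
}

#' Incremental cost-effectiveness ratio
#'
#' Computes delta-cost / delta-QALY of the intervention over the comparator
#' with explicit cost-effectiveness-plane quadrant classification:
#' `"ICER"` (a meaningful ratio: more effective, or the southwest trade-off
#' flagged via `southwest`), `"DOMINANT"` (cheaper and more effective),
#' `"DOMINATED"` (costlier and less effective), `"ZERO_EFFECT"`
#' (|delta-QALY| below 1e-12; ratio undefined).
#'
#' @param intervention,comparator `dfu_strategy_result` objects from the same
#'   model configuration.
#' @return Object of class `dfu_icer`: list with `delta_cost`, `delta_qaly`,
#'   `icer` (NA unless category is ICER), `category`, `southwest`.
#' @export
icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "dfu_strategy_result"),
            inherits(comparator, "dfu_strategy_result"))
  dc <- intervention$discounted_costs - comparator$discounted_costs
  dq <- intervention$discounted_qalys - comparator$discounted_qalys
  southwest <- FALSE
  if (abs(dq) < 1e-12) {
    category <- "ZERO_EFFECT"
    ratio <- NA_real_
  } else if (dq > 0 && dc <= 0) {
    category <- "DOMINANT"
    ratio <- NA_real_
  } else if (dq < 0 && dc >= 0) {
    category <- "DOMINATED"
    ratio <- NA_real_
  } else {
    category <- "ICER"
    southwest <- dq < 0  # cheaper and less effective: savings per QALY forgone
    ratio <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = ratio,
                 category = category, southwest = southwest),
            class = "dfu_icer")
}

#' @export
print.dfu_icer <- function(x, ...) {
  cat(sprintf("delta cost: %.2f GBP, delta QALYs: %.6f\n", x$delta_cost, x$delta_qaly))
  if (x$category == "ICER") {
    cat(sprintf("ICER: %.0f GBP/QALY%s\n", x$icer,
                if (x$southwest) " (southwest quadrant)" else ""))
  } else {
    cat("category:", x$category, "\n")
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' NMB = wtp * delta-QALY - delta-cost; positive means the intervention is
#' cost-effective at that willingness-to-pay.
#'
#' @param intervention,comparator `dfu_strategy_result` objects.
#' @param wtp willingness-to-pay, GBP per QALY, >= 0.
#' @return NMB in GBP.
#' @export
nmb <- function(intervention, comparator, wtp) {
  stopifnot(inherits(intervention, "dfu_strategy_result"),
            inherits(comparator, "dfu_strategy_result"))
  if (wtp < 0) stop("wtp must be non-negative")
  wtp * (intervention$discounted_qalys - comparator$discounted_qalys) -
    (intervention$discounted_costs - comparator$discounted_costs)
}

#' Evaluate app-plus-care versus standard of care
#'
#' The comparator is the cohort trace under standard of care (relative risk 1,
#' no app cost). The intervention applies [apply_intervention()] with the
#' supplied relative risk and the compliance in `econ`, and adds the app
#' price charged to the surviving cohort. Both arms use identical horizon and
#' discounting.
#'
#' @param params validated `dfu_transitions` (standard-of-care probabilities).
#' @param econ `dfu_econ`.
#' @param config `dfu_config`.
#' @param rr relative risk of recurrence under the intervention, (0, 1].
#' @return List with elements `intervention` and `comparator`, each a
#'   `dfu_strategy_result`.
#' @export
evaluate_strategies <- function(params, econ, config, rr = config$intervention_rr) {
  comp_trace <- run_cohort_trace(params, config)
  comp_out <- accumulate_outcomes(comp_trace, econ, include_app_cost = FALSE)
  int_params <- apply_intervention(params, rr, econ$compliance)
  int_trace <- run_cohort_trace(int_params, config)
  int_out <- accumulate_outcomes(int_trace, econ, include_app_cost = TRUE)
  list(intervention = strategy_result("app + standard of care",
                                      int_out$discounted_qalys,
                                      int_out$discounted_costs),
       comparator = strategy_result("standard of care",
                                    comp_out$discounted_qalys,
                                    comp_out$discounted_costs))
}

# NMB of the intervention at the target wtp as a function of rr; the
# threshold rr* is its root. Also returns the QALY gain so the caller can
# convert the NMB residual into a relative ICER error.
threshold_objective <- function(rr, params, econ, config, target_icer) {
  s <- evaluate_strategies(params, econ, config, rr)
  list(nmb = nmb(s$intervention, s$comparator, target_icer),
       dq = s$intervention$discounted_qalys - s$comparator$discounted_qalys)
}

#' Threshold analysis: relative recurrence reduction attaining a target ICER
#'
#' Finds the relative risk rr* at which the intervention's ICER against
#' standard of care equals `target_icer`, by bisection on the net monetary
#' benefit at the target willingness-to-pay over rr in (eps, 1]. This is the
#' model's key output when comparative effectiveness data are absent: the
#' smallest recurrence reduction the app must deliver to be cost-effective.
#'
#' @param params validated `dfu_transitions`.
#' @param econ `dfu_econ`.
#' @param config `dfu_config`.
#' @param target_icer target ICER in GBP per QALY, > 0.
#' @param tol relative tolerance on the ICER at the returned rr*:
#'   |ICER(rr*) - target| / target < tol.
#' @param max_iter maximum bisection iterations.
#' @param eps lower end of the search interval.
#' @return Object of class `dfu_threshold`: list with `rr` (threshold
#'   relative risk, NA if no threshold), `relative_reduction` (1 - rr),
#'   `icer` (recomputed at rr*), `status` (one of `"ok"`,
#'   `"dominant_at_rr1"`, `"no_threshold"`), and diagnostic NMB endpoints.
#' @export
#' @examples
#' th <- threshold_rr(placeholder_transitions(), economic_parameters(),
#'                    model_config(), target_icer = 20000)
#' th$relative_reduction
threshold_rr <- function(params, econ, config, target_icer = econ$wtp,
                         tol = 1e-6, max_iter = 200, eps = 1e-4) {
  if (target_icer <= 0) stop("target_icer must be positive")
  f_hi <- threshold_objective(1, params, econ, config, target_icer)
  if (f_hi$nmb >= 0) {
    # even a zero-effect app is cost-effective (price 0 boundary)
    return(structure(list(rr = 1, relative_reduction = 0, icer = NA_real_,
                          status = "dominant_at_rr1",
                          nmb_at_rr1 = f_hi$nmb, nmb_at_eps = NA_real_),
                     class = "dfu_threshold"))
  }
  f_lo <- threshold_objective(eps, params, econ, config, target_icer)
  if (f_lo$nmb < 0) {
    return(structure(list(rr = NA_real_, relative_reduction = NA_real_,
                          icer = NA_real_, status = "no_threshold",
                          nmb_at_rr1 = f_hi$nmb, nmb_at_eps = f_lo$nmb),
                     class = "dfu_threshold"))
  }
  lo <- eps; hi <- 1
  rr_star <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- threshold_objective(mid, params, econ, config, target_icer)
    if (f_mid$nmb >= 0) lo <- mid else hi <- mid
    rr_star <- mid
    # |ICER - target| / target = |NMB residual| / (target * delta-QALY)
    if (f_mid$dq > 0 &&
        abs(f_mid$nmb) / (target_icer * f_mid$dq) < tol) break
    if ((hi - lo) < 1e-14) break
  }
  s <- evaluate_strategies(params, econ, config, rr_star)
  ic <- icer(s$intervention, s$comparator)
  structure(list(rr = rr_star, relative_reduction = 1 - rr_star,
                 icer = ic$icer, status = "ok",
                 nmb_at_rr1 = f_hi, nmb_at_eps = f_lo),
            class = "dfu_threshold")
}

#' @export
print.dfu_threshold <- function(x, ...) {
  switch(x$status,
    ok = cat(sprintf(
      "threshold relative risk %.4f (relative reduction %.1f%%), ICER %.0f GBP/QALY\n",
      x$rr, 100 * x$relative_reduction, x$icer)),
    dominant_at_rr1 = cat("intervention is cost-effective even with no effect (rr = 1)\n"),
    no_threshold = cat(sprintf(
      "no threshold in (0, 1]: NMB at target stays negative (%.2f at rr ~ 0)\n",
      x$nmb_at_eps)))
  invisible(x)
}

#' Run pricing scenarios through the threshold analysis
#'
#' For each named pricing option the threshold analysis is re-run with the
#' corresponding app price; everything else is held fixed. A cheaper app
#' needs a smaller recurrence reduction to reach the target ICER.
#'
#' @param params validated `dfu_transitions`.
#' @param econ `dfu_econ` (its `app_price_monthly` is overridden per
#'   scenario).
#' @param config `dfu_config`.
#' @param pricing character vector of pricing options among
#'   `"free"`, `"monthly"`, `"annual"`.
#' @param target_icer target ICER, GBP/QALY.
#' @param label parameter source label recorded in the report.
#' @return data.frame with one row per scenario: scenario, app_price_monthly,
#'   parameter_source, status, threshold_rr, relative_reduction_pct, icer.
#' @export
run_scenarios <- function(params, econ, config,
                          pricing = c("free", "monthly", "annual"),
                          target_icer = econ$wtp, label = "user") {
  rows <- lapply(pricing, function(opt) {
    price <- app_price(opt)  # errors on unknown label
    e <- econ
    e$app_price_monthly <- price
    th <- threshold_rr(params, e, config, target_icer)
    data.frame(scenario = opt, app_price_monthly = price,
               parameter_source = label, status = th$status,
               threshold_rr = th$rr,
               relative_reduction_pct = 100 * th$relative_reduction,
               icer = th$icer)
  })
  do.call(rbind, rows)
}
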