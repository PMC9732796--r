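#' Run the Markov cohort trace
#'
#' Propagates a cohort that starts 100% in the post-DFU state through monthly
#' cycles, `occupancy[c+1] = occupancy[c] %*% P`, until the cohort reaches
#' `max_age_years` or the surviving fraction falls below the residual
#' tolerance.
#'
#' @param params validated `dfu_transitions`.
#' @param config `dfu_config`.
#' @return Object of class `dfu_trace`: list with `occupancy`
#'   ((n_cycles + 1) x 6 matrix, row 1 = cycle 0), `n_cycles`, and the
#'   `config` used.
#' @export
#' @examples
#' tr <- run_cohort_trace(placeholder_transitions(), model_config())
#' head(tr$occupancy)
run_cohort_trace <- function(params, config) {
  stopifnot(inherits(config, "dfu_config"))
  if (!inherits(params, "dfu_transitions") || !isTRUE(params$validated)) {
    stop("params must be a validated dfu_transitions object")
  }
  P <- params$matrix
  states <- dfu_states()
  max_cycles <- floor((config$max_age_years - config$baseline_age_years) * 12)
  if (max_cycles < 1) stop("horizon produces 0 cycles")

  occ <- matrix(0, max_cycles + 1, 6, dimnames = list(NULL, states))
  occ[1, "post_dfu"] <- 1
  v <- occ[1, ]
  n <- 0L
  for (cyc in seq_len(max_cycles)) {
    v <- as.numeric(v %*% P)
    occ[cyc + 1, ] <- v
    n <- cyc
    if ((1 - v[6]) < config$residual_alive_tolerance) break
  }
  structure(list(occupancy = occ[seq_len(n + 1), , drop = FALSE],
                 n_cycles = n, config = config),
            class = "dfu_trace")
}

#' Per-cycle discount factor
#'
#' With the default continuous-per-cycle convention the factor for cycle `c`
#' is (1 + r)^(-c/12), consistent with an annual rate r applied smoothly
#' across monthly cycles. `"annual_step"` uses the conventional yearly step
#' (1 + r)^(-floor(c/12)).
#'
#' @param cycle cycle index (0 = model start), vectorised.
#' @param annual_rate annual discount rate, >= 0.
#' @param method discounting convention.
#' @return Discount factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(12, 0.035)  # one year out: 1/1.035
discount_factor <- function(cycle, annual_rate,
                            method = c("continuous", "annual_step")) {
  method <- match.arg(method)
  if (any(cycle < 0)) stop("cycle must be non-negative")
  if (annual_rate < 0) stop("annual_rate must be non-negative")
  expo <- switch(method, continuous = cycle / 12, annual_step = floor(cycle / 12))
  (1 + annual_rate)^(-expo)
}

#' Accumulate discounted QALYs and costs over a cohort trace
#'
#' For each cycle the QALY increment is the utility-weighted occupancy times
#' 1/12 year, and the cost increment is the occupancy-weighted monthly state
#' cost, optionally plus the app price charged to the surviving fraction.
#' Both are discounted with the configured convention (rates may differ
#' between outcomes and costs). With the half-cycle correction the occupancy
#' used for cycle c is the average of the start- and end-of-cycle rows;
#' without it the end-of-cycle row is used.
#'
#' @param trace `dfu_trace` from [run_cohort_trace()].
#' @param econ `dfu_econ`.
#' @param include_app_cost logical; charge `app_price_monthly` to the alive
#'   fraction each cycle.
#' @return List with `discounted_qalys` and `discounted_costs`.
#' @export
accumulate_outcomes <- function(trace, econ, include_app_cost = FALSE) {
  stopifnot(inherits(trace, "dfu_trace"), inherits(econ, "dfu_econ"))
  occ <- trace$occupancy
  if (!identical(colnames(occ), names(econ$utilities))) {
    stop("state sets of trace and economic parameters do not match")
  }
  n <- trace$n_cycles
  if (n < 1) return(list(discounted_qalys = 0, discounted_costs = 0))
  cfg <- trace$config

  end_rows <- occ[2:(n + 1), , drop = FALSE]
  if (cfg$half_cycle_correction) {
    used <- (occ[1:n, , drop = FALSE] + end_rows) / 2
  } else {
    used <- end_rows
  }
  cycles <- seq_len(n)
  d_out <- discount_factor(cycles, econ$discount_outcomes, cfg$discounting)
  d_cost <- discount_factor(cycles, econ$discount_costs, cfg$discounting)

  qalys <- sum((used %*% econ$utilities) * (1 / 12) * d_out)
  costs <- sum((used %*% econ$monthly_costs) * d_cost)
  if (isTRUE(include_app_cost)) {
    alive <- 1 - used[, "death"]
    costs <- costs + sum(econ$app_price_monthly * alive * d_cost)
  }
  list(discounted_qalys = qalys, discounted_costs = costs)
}

#' @export
print.dfu_trace <- function(x, ...) {
  cat("DFU Markov cohort trace:", x$n_cycles, "monthly cycles",
      sprintf("(age %.1f to %.1f years)\n", x$config$baseline_age_years,
              x$config$baseline_age_years + x$n_cycles / 12))
  cat("final occupancy:\n")
  print(round(x$occupancy[x$n_cycles + 1, ], 6))
  invisible(x)
}

#' Convert a trace to a data frame
#'
#' One row per cycle with the age, state occupancy proportions and the
#' discount factors that [accumulate_outcomes()] would apply.
#'
#' @param x `dfu_trace`.
#' @param econ `dfu_econ` supplying the discount rates (defaults to
#'   base-case 3.5%/3.5%).
#' @param ... unused.
#' @return data.frame with columns cycle, age_years, the six states,
#'   discount_out and discount_cost.
#' @export
as.data.frame.dfu_trace <- function(x, econ = economic_parameters(), ...) {
  cycles <- 0:x$n_cycles
  data.frame(cycle = cycles,
             age_years = x$config$baseline_age_years + cycles / 12,
             x$occupancy,
             discount_out = discount_factor(cycles, econ$discount_outcomes,
                                            x$config$discounting),
             discount_cost = discount_factor(cycles, econ$discount_costs,
                                             x$config$discounting),
             check.names = FALSE)
}
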