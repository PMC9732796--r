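# Parameter addressing for sensitivity analysis and config files.
# Names resolve as:
#   transitions.<from>.to.<to>   monthly transition probability
#   utilities.<state>            state utility (QALY weight)
#   costs.<state>                monthly state cost, GBP
#   costs.app_monthly            app price, GBP per month
#   model.compliance             app compliance proportion
#   model.discount_outcomes      annual discount rate, outcomes
#   model.discount_costs         annual discount rate, costs
resolve_parameter <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  states <- dfu_states()
  if (length(parts) == 4 && parts[1] == "transitions" && parts[3] == "to" &&
      all(parts[c(2, 4)] %in% states)) {
    return(list(kind = "transition", from = parts[2], to = parts[4]))
  }
  if (length(parts) == 2 && parts[1] == "utilities" && parts[2] %in% states) {
    return(list(kind = "utility", state = parts[2]))
  }
  if (length(parts) == 2 && parts[1] == "costs") {
    if (parts[2] %in% states) return(list(kind = "cost", state = parts[2]))
    if (parts[2] == "app_monthly") return(list(kind = "app_price"))
  }
  if (length(parts) == 2 && parts[1] == "model" &&
      parts[2] %in% c("compliance", "discount_outcomes", "discount_costs")) {
    return(list(kind = parts[2]))
  }
  stop("cannot resolve parameter name '", name, "'")
}

# Returns list(params, econ) with the named parameter set to `value`.
# Probabilities are clipped to [0, 1] with a warning; utilities and costs
# outside their domains are errors.
set_model_parameter <- function(name, value, params, econ) {
  r <- resolve_parameter(name)
  clip_prob <- function(v, what) {
    if (v < 0 || v > 1) {
      warning(what, " clipped to [0, 1] (was ", format(v), ")")
      v <- min(max(v, 0), 1)
    }
    v
  }
  if (r$kind == "transition") {
    if (r$to == residual_target()[[r$from]]) {
      stop("transition ", r$from, " -> ", r$to,
           " is the row's derived residual and cannot be set directly")
    }
    v <- clip_prob(value, name)
    P <- params$matrix
    P[r$from, r$to] <- v
    P[r$from, residual_target()[[r$from]]] <- 0
    params$matrix <- P
    params <- validate_transitions(params)
  } else if (r$kind == "utility") {
    if (value < 0 || value > 1) stop("utility out of [0, 1]: ", name)
    if (r$state == "death" && value != 0) stop("utility of death must be 0")
    econ$utilities[[r$state]] <- value
  } else if (r$kind == "cost") {
    if (value < 0) stop("negative cost: ", name)
    econ$monthly_costs[[r$state]] <- value
  } else if (r$kind == "app_price") {
    if (value < 0) stop("negative app price")
    econ$app_price_monthly <- value
  } else if (r$kind == "compliance") {
    econ$compliance <- clip_prob(value, name)
  } else if (r$kind == "discount_outcomes") {
    if (value < 0 || value >= 0.5) stop("discount rate out of [0, 0.5): ", name)
    econ$discount_outcomes <- value
  } else if (r$kind == "discount_costs") {
    if (value < 0 || value >= 0.5) stop("discount rate out of [0, 0.5): ", name)
    econ$discount_costs <- value
  }
  list(params = params, econ = econ)
}

# Current value of a named parameter.
get_model_parameter <- function(name, params, econ) {
  r <- resolve_parameter(name)
  switch(r$kind,
         transition = params$matrix[r$from, r$to],
         utility = econ$utilities[[r$state]],
         cost = econ$monthly_costs[[r$state]],
         app_price = econ$app_price_monthly,
         compliance = econ$compliance,
         discount_outcomes = econ$discount_outcomes,
         discount_costs = econ$discount_costs)
}

#' Default one-way sensitivity ranges
#'
#' Conventional deterministic-sensitivity defaults: +/-20% of the base value
#' for transition probabilities, utilities, costs, the app price and
#' compliance (clipped to valid domains), and an absolute 1.5%-6% band for
#' the two discount rates. Every range can be overridden by passing an
#' explicit table to [owsa()].
#'
#' @param params validated `dfu_transitions`.
#' @param econ `dfu_econ`.
#' @return data.frame with columns name, base, low, high.
#' @export
default_owsa_ranges <- function(params, econ) {
  states <- dfu_states()
  mask <- params$mask
  res <- residual_target()
  rows <- list()
  add <- function(name, base, low, high) {
    rows[[length(rows) + 1]] <<- data.frame(name = name, base = base,
                                            low = low, high = high)
  }
  for (from in states) {
    for (to in states[mask[from, ] & states != res[[from]]]) {
      b <- params$matrix[from, to]
      if (b > 0) {
        add(paste0("transitions.", from, ".to.", to), b,
            max(0, 0.8 * b), min(1, 1.2 * b))
      }
    }
  }
  for (s in setdiff(states, "death")) {
    u <- econ$utilities[[s]]
    add(paste0("utilities.", s), u, max(0, 0.8 * u), min(1, 1.2 * u))
    cst <- econ$monthly_costs[[s]]
    add(paste0("costs.", s), cst, 0.8 * cst, 1.2 * cst)
  }
  add("costs.app_monthly", econ$app_price_monthly,
      0.8 * econ$app_price_monthly, 1.2 * econ$app_price_monthly)
  add("model.compliance", econ$compliance,
      max(0, 0.8 * econ$compliance), min(1, 1.2 * econ$compliance))
  add("model.discount_outcomes", econ$discount_outcomes, 0.015, 0.06)
  add("model.discount_costs", econ$discount_costs, 0.015, 0.06)
  do.call(rbind, rows)
}

#' One-way sensitivity analysis (tornado)
#'
#' Recomputes the intervention-versus-standard-of-care net monetary benefit
#' with each parameter set to its low and to its high value, all others at
#' base; each endpoint is an independent full model evaluation. Bars are
#' returned sorted by descending width (tornado order), ties broken
#' alphabetically, so output is deterministic and invariant to input order.
#'
#' @param params validated `dfu_transitions`.
#' @param econ `dfu_econ`.
#' @param config `dfu_config`.
#' @param ranges data.frame with columns name, base, low, high; defaults to
#'   [default_owsa_ranges()].
#' @param rr relative risk of recurrence under the intervention.
#' @param wtp willingness-to-pay used for the NMB, GBP/QALY.
#' @return data.frame of class `dfu_tornado` with columns parameter, base,
#'   low, high, nmb_low, nmb_high, width.
#' @export
owsa <- function(params, econ, config,
                 ranges = default_owsa_ranges(params, econ),
                 rr = config$intervention_rr, wtp = econ$wtp) {
  stopifnot(is.data.frame(ranges),
            all(c("name", "base", "low", "high") %in% names(ranges)))
  if (anyDuplicated(ranges$name)) {
    stop("duplicated parameter entries in ranges: ",
         paste(unique(ranges$name[duplicated(ranges$name)]), collapse = ", "))
  }
  if (any(ranges$low > ranges$base | ranges$base > ranges$high)) {
    bad <- ranges$name[ranges$low > ranges$base | ranges$base > ranges$high]
    stop("range must satisfy low <= base <= high: ", paste(bad, collapse = ", "))
  }
  eval_at <- function(name, value) {
    m <- set_model_parameter(name, value, params, econ)
    s <- evaluate_strategies(m$params, m$econ, config, rr)
    nmb(s$intervention, s$comparator, wtp)
  }
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    nm <- ranges$name[i]
    resolve_parameter(nm)  # fail fast on unknown names
    lo <- eval_at(nm, ranges$low[i])
    hi <- eval_at(nm, ranges$high[i])
    data.frame(parameter = nm, base = ranges$base[i],
               low = ranges$low[i], high = ranges$high[i],
               nmb_low = lo, nmb_high = hi, width = abs(hi - lo))
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$width, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dfu_tornado", "data.frame")
  out
}

#' Plot a tornado diagram
#'
#' Horizontal bars of the NMB range per parameter, widest on top, around the
#' base-case NMB.
#'
#' @param tornado output of [owsa()].
#' @param nmb_base base-case NMB drawn as a reference line (optional).
#' @param top show only the `top` widest bars.
#' @param ... passed to [graphics::barplot()]-style drawing (unused).
#' @return Invisibly, the plotted subset.
#' @export
plot_tornado <- function(tornado, nmb_base = NULL, top = 12, ...) {
  tor <- utils::head(tornado, top)
  tor <- tor[rev(seq_len(nrow(tor))), ]
  lo <- pmin(tor$nmb_low, tor$nmb_high)
  hi <- pmax(tor$nmb_low, tor$nmb_high)
  old <- graphics::par(mar = c(4.5, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA, xlim = range(c(lo, hi, nmb_base)), ylim = c(0.5, nrow(tor) + 0.5),
                 xlab = "net monetary benefit (GBP)", ylab = "", yaxt = "n",
                 main = "One-way sensitivity analysis")
  graphics::rect(lo, seq_len(nrow(tor)) - 0.35, hi, seq_len(nrow(tor)) + 0.35,
                 col = "steelblue", border = NA)
  graphics::axis(2, at = seq_len(nrow(tor)), labels = tor$parameter, las = 1,
                 cex.axis = 0.7)
  if (!is.null(nmb_base)) graphics::abline(v = nmb_base, lty = 2)
  invisible(tor)
}
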