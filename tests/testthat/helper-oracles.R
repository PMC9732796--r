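# Independent oracles used across test files.

# Product-limit (Kaplan-Meier) restricted mean, hand-coded: integrate the
# step survival curve S(t) from 0 to tmax.
km_rmean_oracle <- function(times, events, tmax = max(times)) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  uniq <- sort(unique(times[events == 1]))
  S <- 1
  curve_t <- 0
  curve_s <- 1
  for (t in uniq) {
    at_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    S <- S * (1 - d / at_risk)
    curve_t <- c(curve_t, t)
    curve_s <- c(curve_s, S)
  }
  grid <- c(curve_t[curve_t <= tmax], tmax)
  s_at <- function(t) curve_s[max(which(curve_t <= t))]
  area <- 0
  for (i in seq_len(length(grid) - 1)) {
    area <- area + s_at(grid[i]) * (grid[i + 1] - grid[i])
  }
  area
}

# Two-pass textbook mean/SD oracle.
mean_sd_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}

# Grid-search oracle for the threshold relative risk: the smallest NMB-
# non-negative rr on a uniform grid (NMB at the target willingness-to-pay is
# non-increasing in rr when the app carries a positive price).
threshold_grid_oracle <- function(params, econ, config, target_icer,
                                  grid = seq(0.001, 1, by = 0.001)) {
  comp_trace <- run_cohort_trace(params, config)
  comp <- accumulate_outcomes(comp_trace, econ, include_app_cost = FALSE)
  nmb_at <- vapply(grid, function(rr) {
    ip <- apply_intervention(params, rr, econ$compliance)
    it <- run_cohort_trace(ip, config)
    io <- accumulate_outcomes(it, econ, include_app_cost = TRUE)
    target_icer * (io$discounted_qalys - comp$discounted_qalys) -
      (io$discounted_costs - comp$discounted_costs)
  }, numeric(1))
  ok <- which(nmb_at >= 0)
  if (!length(ok)) return(NA_real_)
  grid[max(ok)]
}

random_params <- function(seed) generate_transition_params(seed = seed)
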