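# Seed-splitting: each generator derives an independent stream from the user
# seed with a fixed small offset, so cohorts and patient histories produced
# from the same master seed are individually reproducible.
derive_seed <- function(seed, stream) {
  (as.integer(seed) + stream * 10007L) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic cohort generator
#'
#' Defaults emulate the feasibility cohort's marginal distributions: age
#' normal(60.8, 9.3) truncated to \[18, 95\] years, BMI normal(32.94, 6.13)
#' truncated to \[15, 60\], 3/15 female, 12/15 type 2 diabetes, smoking
#' Current/Previous/Never with probabilities 1/15, 9/15, 5/15, six SINBAD
#' components Bernoulli(0.35) each (expected total 2.1), and recurrence
#' times geometric from a monthly hazard of 0.06 (so roughly half the cohort
#' recurs within a year, as observed), administratively censored at 364 days
#' (52 weeks of follow-up).
#'
#' @param n cohort size, >= 1.
#' @param seed integer master seed.
#' @param age_mean,age_sd age distribution (years).
#' @param bmi_mean,bmi_sd BMI distribution (kg/m2).
#' @param p_female,p_t2dm marginal probabilities.
#' @param smoking_probs named probabilities for Current/Previous/Never
#'   (must sum to 1).
#' @param sinbad_component_probs six Bernoulli probabilities for the SINBAD
#'   components.
#' @param monthly_recurrence_hazard per-month probability of reulceration.
#' @param followup_days administrative censoring time (days).
#' @return List of class `dfu_cohort_spec`.
#' @export
cohort_generator_spec <- function(n, seed = 1,
                                  age_mean = 60.8, age_sd = 9.3,
                                  bmi_mean = 32.94, bmi_sd = 6.13,
                                  p_female = 3 / 15, p_t2dm = 12 / 15,
                                  smoking_probs = c(Current = 1 / 15,
                                                    Previous = 9 / 15,
                                                    Never = 5 / 15),
                                  sinbad_component_probs = rep(0.35, 6),
                                  monthly_recurrence_hazard = 0.06,
                                  followup_days = 364) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  probs <- c(p_female, p_t2dm, smoking_probs, sinbad_component_probs,
             monthly_recurrence_hazard)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(smoking_probs) - 1) > 1e-9) stop("smoking_probs must sum to 1")
  if (length(sinbad_component_probs) != 6) {
    stop("sinbad_component_probs must have six entries")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 p_female = p_female, p_t2dm = p_t2dm,
                 smoking_probs = smoking_probs,
                 sinbad_component_probs = sinbad_component_probs,
                 monthly_recurrence_hazard = monthly_recurrence_hazard,
                 followup_days = followup_days),
            class = "dfu_cohort_spec")
}

rnorm_truncated <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {                       # redraw out-of-range values
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic feasibility cohort
#'
#' Draws `spec$n` patient records with the cohort schema of [read_cohort()]
#' plus the SINBAD component columns and recurrence outcome fields
#' (`recurrence_day`, `recurrence_event`). The SINBAD total and the
#' reulceration outcome are derived from the sampled components and times,
#' never sampled independently of them. Fully reproducible from the spec's
#' seed.
#'
#' @param spec `dfu_cohort_spec` from [cohort_generator_spec()].
#' @return data.frame of synthetic patient records.
#' @export
#' @examples
#' head(generate_cohort(cohort_generator_spec(n = 5, seed = 42)))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "dfu_cohort_spec"))
  n <- spec$n
  with_seed(derive_seed(spec$seed, 1L), {
    age <- round(rnorm_truncated(n, spec$age_mean, spec$age_sd, 18, 95))
    bmi <- round(rnorm_truncated(n, spec$bmi_mean, spec$bmi_sd, 15, 60), 1)
    gender <- ifelse(stats::runif(n) < spec$p_female, "F", "M")
    dtype <- ifelse(stats::runif(n) < spec$p_t2dm, 2L, 1L)
    smoking <- sample(names(spec$smoking_probs), n, replace = TRUE,
                      prob = spec$smoking_probs)
    comp <- sapply(spec$sinbad_component_probs,
                   function(p) stats::rbinom(n, 1, p))
    comp <- matrix(comp, ncol = 6,
                   dimnames = list(NULL, c("site", "ischemia", "neuropathy",
                                           "bacterial_infection", "area",
                                           "depth")))
    score <- sinbad_total(as.data.frame(comp))

    # reulceration: month of recurrence geometric in the monthly hazard,
    # mapped to days and censored at end of follow-up
    h <- spec$monthly_recurrence_hazard
    if (h > 0) {
      month <- stats::rgeom(n, h) + 1          # first month with recurrence
      day <- pmin(round(month * 30.4375), spec$followup_days + 1)
    } else {
      day <- rep(spec$followup_days + 1, n)
    }
    event <- as.integer(day <= spec$followup_days)
    day <- pmin(day, spec$followup_days)

    data.frame(
      study_id = sprintf("S%04d", seq_len(n)),
      gender = gender, age = age, ethnicity = "English",
      bmi = bmi, employment = "Unknown", smoking = smoking,
      diabetes_type = dtype,
      year_diagnosis = 2022L - stats::rpois(n, 15),
      monofilament_loss = sample(c("None", "Right", "Left", "Both"), n,
                                 replace = TRUE,
                                 prob = c(0.2, 0.05, 0.05, 0.7)),
      as.data.frame(comp),
      sinbad_score = score,
      dfu_study_visits = pmin(7L, 1L + stats::rpois(n, 3)),
      reason_incomplete = ifelse(event == 1, "Reulceration", ""),
      gp_visits = stats::rpois(n, 1),
      outpatient_visits = stats::rpois(n, 1),
      hospital_bed_days = stats::rpois(n, 0.2),
      recurrence_day = day,
      recurrence_event = event,
      stringsAsFactors = FALSE
    )
  })
}

#' Random transition parameter set
#'
#' Draws each allowed outflow uniformly within per-transition bounds,
#' redrawing any row whose outflows would exceed 1, and validates the result.
#' Default bounds are broad but plausible for monthly probabilities in this
#' disease area.
#'
#' @param seed integer seed.
#' @param constraints named list `key = c(lower, upper)` with keys
#'   `"<from>.to.<to>"`; overrides the defaults per transition.
#' @return Validated `dfu_transitions`.
#' @export
generate_transition_params <- function(seed = 1, constraints = list()) {
  defaults <- list(
    "post_dfu.to.nonsevere_dfu"   = c(0.001, 0.05),
    "post_dfu.to.severe_dfu"      = c(0.001, 0.03),
    "post_dfu.to.death"           = c(0.0005, 0.01),
    "nonsevere_dfu.to.post_dfu"   = c(0.05, 0.4),
    "nonsevere_dfu.to.severe_dfu" = c(0.01, 0.15),
    "nonsevere_dfu.to.amputation" = c(0.001, 0.05),
    "severe_dfu.to.post_dfu"      = c(0.02, 0.3),
    "severe_dfu.to.amputation"    = c(0.005, 0.1),
    "severe_dfu.to.death"         = c(0.002, 0.05),
    "post_amputation.to.death"    = c(0.002, 0.03)
  )
  unknown <- setdiff(names(constraints), names(defaults))
  if (length(unknown)) {
    stop("constraints on unknown/forbidden transition(s): ",
         paste(unknown, collapse = ", "))
  }
  bounds <- utils::modifyList(defaults, constraints)
  for (key in names(bounds)) {
    b <- bounds[[key]]
    if (length(b) != 2 || b[1] > b[2] || b[1] < 0 || b[2] > 1) {
      stop("infeasible bounds for ", key)
    }
  }
  lower_by_row <- tapply(vapply(bounds, `[`, 0, 1),
                         vapply(names(bounds),
                                function(k) parse_transition_key(k)[1], ""),
                         sum)
  if (any(lower_by_row > 1)) {
    stop("infeasible constraints: lower bounds of a row's outflows exceed 1")
  }
  with_seed(derive_seed(seed, 2L), {
    for (attempt in 1:1000) {
      draw <- vapply(bounds, function(b) stats::runif(1, b[1], b[2]), 0)
      names(draw) <- names(bounds)
      ok <- tryCatch({
        params <- transition_parameters(draw)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(params)
    }
    stop("could not draw a feasible parameter set in 1000 attempts")
  })
}

#' Microsimulate individual patient histories
#'
#' Simulates `n` independent patient paths through the six-state chain,
#' starting in the post-DFU state, under the same monthly transition rules as
#' the cohort trace. The per-cycle state frequencies serve as a stochastic
#' oracle for [run_cohort_trace()].
#'
#' @param params validated `dfu_transitions`.
#' @param n number of simulated patients, >= 1.
#' @param seed integer seed.
#' @param n_cycles number of monthly cycles to simulate.
#' @return List with `frequencies` ((n_cycles + 1) x 6 matrix of state
#'   proportions, row 1 = cycle 0), `counts` (same shape, integers), `n`.
#' @export
simulate_patient_histories <- function(params, n, seed = 1, n_cycles = 60) {
  if (!inherits(params, "dfu_transitions") || !isTRUE(params$validated)) {
    stop("params must be a validated dfu_transitions object")
  }
  if (n < 1) stop("n must be >= 1")
  states <- dfu_states()
  P <- params$matrix
  cum <- t(apply(P, 1, cumsum))
  cum[, 6] <- 1                                 # guard the final bin exactly
  with_seed(derive_seed(seed, 3L), {
    state <- rep.int(1L, n)                     # everyone starts post-DFU
    counts <- matrix(0L, n_cycles + 1, 6, dimnames = list(NULL, states))
    counts[1, ] <- tabulate(state, 6)
    for (cyc in seq_len(n_cycles)) {
      u <- stats::runif(n)
      new_state <- integer(n)
      for (s in 1:6) {
        idx <- state == s
        if (any(idx)) {
          # invert the cumulative row distribution
          new_state[idx] <- findInterval(u[idx], cum[s, ],
                                         left.open = TRUE) + 1L
        }
      }
      state <- new_state
      counts[cyc + 1, ] <- tabulate(state, 6)
    }
    list(frequencies = counts / n, counts = counts, n = n)
  })
}
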