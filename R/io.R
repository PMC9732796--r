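#' Load a model parameter file
#'
#' YAML configuration with four sections:
#' \describe{
#'   \item{transitions}{monthly probabilities keyed `"<from>.to.<to>"`, e.g.
#'     `post_dfu.to.nonsevere_dfu: 0.014`. Required and non-empty: there is no
#'     silent fallback to the placeholder set.}
#'   \item{utilities}{state utilities keyed by state name.}
#'   \item{costs}{monthly state costs keyed by state name, plus
#'     `app_monthly`.}
#'   \item{model}{`compliance`, `discount_outcomes`, `discount_costs`, `wtp`,
#'     `baseline_age_years`, `proportion_male`, `max_age_years`,
#'     `residual_alive_tolerance`, `half_cycle_correction`, `discounting`,
#'     `intervention_rr`, `allow_perioperative_death`.}
#' }
#' Unknown keys are errors. Missing utility/cost/model keys fall back to the
#' base-case defaults of [economic_parameters()] and [model_config()], with a
#' notice listing what was defaulted.
#'
#' @param path YAML file path.
#' @param quiet suppress the defaulting notice.
#' @return List with elements `transitions` (`dfu_transitions`), `econ`
#'   (`dfu_econ`) and `config` (`dfu_config`).
#' @export
load_parameters <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  known_sections <- c("transitions", "utilities", "costs", "model")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown)) {
    stop("unknown section(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  tr <- raw$transitions
  if (is.null(tr) || length(tr) == 0) {
    stop("empty or missing [transitions] section in ", path,
         ": transition probabilities must be supplied explicitly")
  }
  allow_pd <- isTRUE(raw$model$allow_perioperative_death)
  params <- transition_parameters(unlist(tr),
                                  allow_perioperative_death = allow_pd)

  defaulted <- character(0)
  states <- dfu_states()

  ed <- economic_parameters()   # base-case defaults
  utilities <- ed$utilities
  if (!is.null(raw$utilities)) {
    bad <- setdiff(names(raw$utilities), states)
    if (length(bad)) stop("unknown utility key(s): ", paste(bad, collapse = ", "))
    utilities[names(raw$utilities)] <- unlist(raw$utilities)
  }
  defaulted <- c(defaulted, paste0("utilities.",
                                   setdiff(states, names(raw$utilities))))

  costs <- ed$monthly_costs
  app_price <- ed$app_price_monthly
  if (!is.null(raw$costs)) {
    bad <- setdiff(names(raw$costs), c(states, "app_monthly"))
    if (length(bad)) stop("unknown cost key(s): ", paste(bad, collapse = ", "))
    keep <- intersect(names(raw$costs), states)
    costs[keep] <- unlist(raw$costs[keep])
    if (!is.null(raw$costs$app_monthly)) app_price <- raw$costs$app_monthly
  }
  defaulted <- c(defaulted,
                 paste0("costs.", setdiff(c(states, "app_monthly"),
                                          names(raw$costs))))

  model_keys <- c("compliance", "discount_outcomes", "discount_costs", "wtp",
                  "baseline_age_years", "proportion_male", "max_age_years",
                  "residual_alive_tolerance", "half_cycle_correction",
                  "discounting", "intervention_rr", "allow_perioperative_death")
  if (!is.null(raw$model)) {
    bad <- setdiff(names(raw$model), model_keys)
    if (length(bad)) stop("unknown model key(s): ", paste(bad, collapse = ", "))
  }
  mv <- function(key, default) {
    if (!is.null(raw$model[[key]])) raw$model[[key]] else default
  }
  econ <- economic_parameters(
    utilities = utilities, monthly_costs = costs,
    app_price_monthly = app_price,
    compliance = mv("compliance", ed$compliance),
    discount_outcomes = mv("discount_outcomes", ed$discount_outcomes),
    discount_costs = mv("discount_costs", ed$discount_costs),
    wtp = mv("wtp", ed$wtp))
  config <- model_config(
    baseline_age_years = mv("baseline_age_years", 67),
    proportion_male = mv("proportion_male", 0.70),
    max_age_years = mv("max_age_years", 100),
    residual_alive_tolerance = mv("residual_alive_tolerance", 1e-6),
    half_cycle_correction = mv("half_cycle_correction", TRUE),
    discounting = mv("discounting", "continuous"),
    intervention_rr = mv("intervention_rr", 1))

  defaulted <- c(defaulted, paste0("model.",
                                   setdiff(model_keys,
                                           c(names(raw$model),
                                             "allow_perioperative_death"))))
  if (!quiet && length(defaulted)) {
    message("using base-case defaults for: ", paste(defaulted, collapse = ", "))
  }
  list(transitions = params, econ = econ, config = config)
}

#' Write a parameter bundle back to a YAML file
#'
#' Inverse of [load_parameters()]: writing a bundle and reloading it yields
#' identical transition, economic and model parameters.
#'
#' @param bundle list with `transitions`, `econ`, `config` as returned by
#'   [load_parameters()].
#' @param path output YAML path.
#' @return Invisibly, `path`.
#' @export
write_parameters <- function(bundle, path) {
  params <- bundle$transitions
  states <- dfu_states()
  res <- residual_target()
  tr <- list()
  for (from in states) {
    for (to in states[params$mask[from, ] & states != res[[from]]]) {
      v <- params$matrix[from, to]
      if (v > 0) tr[[paste0(from, ".to.", to)]] <- v
    }
  }
  e <- bundle$econ; cfg <- bundle$config
  out <- list(
    transitions = tr,
    utilities = as.list(e$utilities),
    costs = c(as.list(e$monthly_costs), list(app_monthly = e$app_price_monthly)),
    model = list(compliance = e$compliance,
                 discount_outcomes = e$discount_outcomes,
                 discount_costs = e$discount_costs, wtp = e$wtp,
                 baseline_age_years = cfg$baseline_age_years,
                 proportion_male = cfg$proportion_male,
                 max_age_years = cfg$max_age_years,
                 residual_alive_tolerance = cfg$residual_alive_tolerance,
                 half_cycle_correction = cfg$half_cycle_correction,
                 discounting = cfg$discounting,
                 intervention_rr = cfg$intervention_rr,
                 allow_perioperative_death = params$allow_perioperative_death))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run manifest
#'
#' Provenance block embedded as a comment header in every written report:
#' package version, seed(s) and MD5 digests of the input files. Wall-clock
#' timestamps are deliberately excluded so identical inputs produce
#' byte-identical reports.
#'
#' @param inputs character vector of input file paths (digested if they
#'   exist).
#' @param seed seed(s) used, if any.
#' @return Named character vector of manifest fields.
#' @export
run_manifest <- function(inputs = character(0), seed = NA) {
  m <- c(package = "dfuheor",
         version = as.character(utils::packageVersion("dfuheor")),
         seed = paste(seed, collapse = ","))
  for (f in inputs) {
    if (file.exists(f)) {
      m[paste0("input:", basename(f))] <- unname(tools::md5sum(f))
    }
  }
  m
}

format_num <- function(x) {
  ifelse(is.na(x), "", trimws(formatC(x, digits = 6, format = "g")))
}

# Core CSV report writer: '#'-prefixed manifest header, fixed column order,
# 6 significant digits. Empty frames produce a header-only file with a
# warning.
write_csv_report <- function(df, path, manifest = run_manifest()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(manifest), ": ", manifest), con)
  if (nrow(df) == 0) warning("empty results set: writing header-only report")
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort trace to CSV
#'
#' Columns: cycle, age_years, the six states, discount_out, discount_cost,
#' preceded by a manifest comment header.
#'
#' @param trace `dfu_trace`.
#' @param path output path.
#' @param econ `dfu_econ` for the discount columns.
#' @param manifest from [run_manifest()].
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path, econ = economic_parameters(),
                            manifest = run_manifest()) {
  write_csv_report(as.data.frame(trace, econ = econ), path, manifest)
}

#' Write a tornado table to CSV
#'
#' @param tornado output of [owsa()].
#' @param path output path.
#' @param manifest from [run_manifest()].
#' @return Invisibly, `path`.
#' @export
write_tornado_csv <- function(tornado, path, manifest = run_manifest()) {
  write_csv_report(as.data.frame(tornado), path, manifest)
}

#' Write a threshold/scenario report
#'
#' One row per pricing scenario with the threshold relative risk and the
#' relative reduction printed to one decimal percent.
#'
#' @param scenarios data.frame from [run_scenarios()].
#' @param path output path.
#' @param manifest from [run_manifest()].
#' @return Invisibly, `path`.
#' @export
write_threshold_report <- function(scenarios, path, manifest = run_manifest()) {
  df <- scenarios
  df$relative_reduction <- ifelse(
    is.na(df$threshold_rr), "",
    sprintf("%.1f%%", df$relative_reduction_pct))
  df$relative_reduction_pct <- NULL
  write_csv_report(df, path, manifest)
}

#' Write a cohort summary table
#'
#' @param summary data.frame from [summarize_cohort()].
#' @param path output path.
#' @param manifest from [run_manifest()].
#' @return Invisibly, `path`.
#' @export
write_cohort_summary <- function(summary, path, manifest = run_manifest()) {
  write_csv_report(summary, path, manifest)
}

#' Write a cohort table to CSV (no manifest header, re-readable)
#'
#' @param cohort data.frame (e.g. from [generate_cohort()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
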