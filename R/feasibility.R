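#' Total SINBAD score
#'
#' SINBAD grades an ulcer on six binary components — Site (mid/hindfoot),
#' Ischemia, Neuropathy, Bacterial infection, Area (>= 1 cm2) and Depth
#' (beyond skin/subcutaneous tissue) — each scored 0/1; the total ranges 0-6.
#'
#' @param components data.frame or named list with columns/fields `site`,
#'   `ischemia`, `neuropathy`, `bacterial_infection`, `area`, `depth`, each
#'   0 or 1 (vectorised over rows).
#' @return Integer score(s) in 0..6.
#' @export
#' @examples
#' sinbad_total(data.frame(site = 1, ischemia = 1, neuropathy = 0,
#'                         bacterial_infection = 0, area = 0, depth = 0))
sinbad_total <- function(components) {
  fields <- c("site", "ischemia", "neuropathy", "bacterial_infection",
              "area", "depth")
  if (!all(fields %in% names(components))) {
    stop("components must supply: ", paste(fields, collapse = ", "))
  }
  m <- sapply(fields, function(f) as.numeric(components[[f]]))
  m <- matrix(m, ncol = 6)
  if (anyNA(m) || any(!m %in% c(0, 1))) {
    stop("SINBAD components must be binary 0/1")
  }
  as.integer(rowSums(m))
}

#' Classify ulcer severity from the SINBAD score
#'
#' An ulcer is severe when its SINBAD score is >= 3, non-severe when < 3.
#'
#' @param score integer score(s) in 0..6.
#' @return Character vector, `"severe"` or `"non-severe"`.
#' @export
#' @examples
#' classify_severity(c(2, 3))
classify_severity <- function(score) {
  if (anyNA(score) || any(score != as.integer(score)) ||
      any(score < 0 | score > 6)) {
    stop("SINBAD score must be an integer in 0..6")
  }
  ifelse(score >= 3, "severe", "non-severe")
}

#' Mean and sample standard deviation of a numeric column
#'
#' Missing values are excluded and counted. The standard deviation uses the
#' sample (n - 1) convention; no rounding is applied (presentation layers
#' round).
#'
#' @param values numeric vector.
#' @return List with `mean`, `sd` (NA when n = 1), `n` (values used) and
#'   `n_missing`.
#' @export
summarize_numeric <- function(values) {
  n_missing <- sum(is.na(values))
  x <- values[!is.na(values)]
  if (length(x) == 0) stop("no non-missing values to summarise")
  list(mean = mean(x),
       sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
       n = length(x), n_missing = n_missing)
}

#' Count records matching a predicate
#'
#' The predicate is an unquoted expression evaluated over the cohort table's
#' columns (only columns and base functions are visible, so a reference to an
#' unknown field is an error).
#'
#' @param records cohort data.frame (see [read_cohort()]).
#' @param predicate unquoted logical expression, e.g. `smoking == "Previous"`.
#' @return List with `count`, `n` and `proportion`.
#' @export
#' @examples
#' count_by(dfu_cohort(), gender == "F")
count_by <- function(records, predicate) {
  stopifnot(is.data.frame(records))
  expr <- substitute(predicate)
  hits <- eval(expr, records, baseenv())
  if (!is.logical(hits) || length(hits) != nrow(records)) {
    stop("predicate must evaluate to one logical per record")
  }
  k <- sum(hits, na.rm = TRUE)
  list(count = k, n = nrow(records), proportion = k / nrow(records))
}

# Kaplan-Meier restricted mean survival time up to tmax, via the survival
# package.
km_restricted_mean <- function(times, events, tmax = max(times)) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tab <- summary(fit, rmean = tmax)$table
  unname(tab[[grep("rmean", names(tab), fixed = TRUE)[1]]])
}

#' Ulcer-free time: restricted mean with bootstrap confidence interval
#'
#' Estimates the mean time from healing of the last ulcer to recurrence as
#' the Kaplan-Meier restricted mean survival time (restricted to the largest
#' observed time, so administrative censoring at the end of follow-up is
#' handled), with a nonparametric bootstrap percentile 95% confidence
#' interval. The point estimate does not depend on the seed; only the CI
#' resampling does.
#'
#' @param times positive follow-up times in days.
#' @param events 1 = recurrence observed, 0 = censored.
#' @param n_boot number of bootstrap resamples for the CI.
#' @param seed integer seed for the bootstrap (RNG state is restored on
#'   exit).
#' @param conf confidence level.
#' @return List with `mean_days`, `ci_low`, `ci_high`, `n`, `n_events`,
#'   `restriction_days`.
#' @export
ulcer_free_time_summary <- function(times, events, n_boot = 2000, seed = 1,
                                    conf = 0.95) {
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0 (censored) or 1")
  if (length(times) != length(events)) stop("times and events lengths differ")
  tmax <- max(times)
  est <- km_restricted_mean(times, events, tmax)
  if (sum(events) == 0) {
    warning("all observations censored: restricted mean equals the ",
            "restriction time; confidence interval suppressed")
    return(list(mean_days = est, ci_low = NA_real_, ci_high = NA_real_,
                n = length(times), n_events = 0, restriction_days = tmax))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- length(times)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(events[idx]) == 0) return(NA_real_)
    km_restricted_mean(times[idx], events[idx], tmax)
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  list(mean_days = est, ci_low = ci[1], ci_high = ci[2],
       n = n, n_events = sum(events), restriction_days = tmax)
}

#' Read a feasibility cohort table
#'
#' CSV with one row per patient and the baseline-characteristics schema:
#' study_id, gender, age, ethnicity, bmi, employment, smoking, diabetes_type,
#' year_diagnosis, monofilament_loss, sinbad_score, dfu_study_visits,
#' reason_incomplete (empty = completed the study), gp_visits,
#' outpatient_visits, hospital_bed_days. Extra columns (e.g. synthetic
#' recurrence fields) are preserved.
#'
#' @param path CSV file path.
#' @return data.frame with validated columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(study_id = "character"))
  required <- c("study_id", "gender", "age", "ethnicity", "bmi", "employment",
                "smoking", "diabetes_type", "year_diagnosis",
                "monofilament_loss", "sinbad_score", "dfu_study_visits",
                "reason_incomplete", "gp_visits", "outpatient_visits",
                "hospital_bed_days")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$reason_incomplete[is.na(df$reason_incomplete)] <- ""
  if (any(df$age <= 0) || any(df$bmi <= 0)) stop("age and bmi must be positive")
  if (any(df$sinbad_score < 0 | df$sinbad_score > 6)) {
    stop("sinbad_score must lie in 0..6")
  }
  counts <- c("dfu_study_visits", "gp_visits", "outpatient_visits",
              "hospital_bed_days")
  if (any(as.matrix(df[counts]) < 0)) stop("visit counts must be non-negative")
  df
}

#' The packaged feasibility cohort (15 patients)
#'
#' Per-patient baseline characteristics of the 15-patient full analysis set,
#' transcribed from the published table: demographics, smoking, diabetes type
#' and year of diagnosis, monofilament sensation loss, SINBAD score of the
#' most recent ulcer, study visits, reason for incompletion and
#' resource-use counts.
#'
#' @return data.frame of 15 patient records.
#' @export
#' @examples
#' summarize_cohort(dfu_cohort())
dfu_cohort <- function() {
  read_cohort(system.file("extdata", "feasibility_cohort.csv",
                          package = "dfuheor", mustWork = TRUE))
}

#' Standard feasibility-cohort summary
#'
#' Recomputes the baseline summary statistics reported for the feasibility
#' cohort: mean (SD) of age, BMI and SINBAD score; counts of women, type 2
#' diabetes, previous smokers, severe last ulcers (SINBAD >= 3), study
#' completers and reulcerations.
#'
#' @param records cohort data.frame (see [read_cohort()]).
#' @return data.frame with columns statistic, value, n.
#' @export
summarize_cohort <- function(records) {
  num <- function(stat, value) data.frame(statistic = stat, value = value,
                                          n = nrow(records))
  s_age <- summarize_numeric(records$age)
  s_bmi <- summarize_numeric(records$bmi)
  s_sin <- summarize_numeric(records$sinbad_score)
  rbind(
    num("mean_age_years", s_age$mean),
    num("sd_age_years", s_age$sd),
    num("mean_bmi", s_bmi$mean),
    num("sd_bmi", s_bmi$sd),
    num("mean_sinbad", s_sin$mean),
    num("sd_sinbad", s_sin$sd),
    num("n_female", count_by(records, gender == "F")$count),
    num("n_t2dm", count_by(records, diabetes_type == 2)$count),
    num("n_previous_smokers", count_by(records, smoking == "Previous")$count),
    num("n_current_smokers", count_by(records, smoking == "Current")$count),
    num("n_severe_last_dfu", count_by(records, sinbad_score >= 3)$count),
    num("n_completed", count_by(records, reason_incomplete == "")$count),
    num("n_reulcerated", count_by(records, reason_incomplete == "Reulceration")$count)
  )
}
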