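#' Construct per-cycle transition parameters
#'
#' Builds a validated set of monthly transition probabilities for the
#' six-state model. Probabilities are supplied as a named numeric vector with
#' keys of the form `"<from>.to.<to>"`, e.g. `"post_dfu.to.nonsevere_dfu"`.
#' Only outflows are supplied; the remaining probability mass of each row is
#' assigned automatically to the row's residual state (the state itself for
#' ordinary states, `post_amputation` for the one-cycle amputation tunnel).
#'
#' @param probs named numeric vector of outflow probabilities; may be empty
#'   (every state then self-loops, i.e. an identity chain).
#' @param allow_perioperative_death logical; permit an explicit
#'   `amputation.to.death` entry. Departs from the default model structure and
#'   triggers a warning.
#' @return An object of class `dfu_transitions`: list with elements `matrix`
#'   (6 x 6 row-stochastic), `mask` (logical allowed-transition matrix) and
#'   `validated` (TRUE).
#' @seealso [validate_transitions()], [apply_intervention()],
#'   [placeholder_transitions()]
#' @export
#' @examples
#' p <- transition_parameters(c(
#'   "post_dfu.to.nonsevere_dfu" = 0.014,
#'   "post_dfu.to.severe_dfu"    = 0.006,
#'   "post_dfu.to.death"         = 0.002
#' ))
#' p$matrix["post_dfu", ]
transition_parameters <- function(probs = numeric(0),
                                  allow_perioperative_death = FALSE) {
  states <- dfu_states()
  mask <- structural_mask(allow_perioperative_death)
  P <- matrix(0, 6, 6, dimnames = list(states, states))
  if (length(probs)) {
    if (is.null(names(probs)) || any(!nzchar(names(probs)))) {
      stop("transition probabilities must be a named vector ('<from>.to.<to>')")
    }
    if (anyDuplicated(names(probs))) {
      stop("duplicated transition key(s): ",
           paste(unique(names(probs)[duplicated(names(probs))]), collapse = ", "))
    }
    for (key in names(probs)) {
      ft <- parse_transition_key(key)
      P[ft[1], ft[2]] <- probs[[key]]
    }
  }
  x <- structure(list(matrix = P, mask = mask,
                      allow_perioperative_death = isTRUE(allow_perioperative_death),
                      validated = FALSE),
                 class = "dfu_transitions")
  validate_transitions(x)
}

parse_transition_key <- function(key) {
  states <- dfu_states()
  parts <- strsplit(key, ".to.", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% states)) {
    stop("cannot parse transition key '", key,
         "'; expected '<from>.to.<to>' with states among: ",
         paste(states, collapse = ", "))
  }
  parts
}

#' Validate and complete a transition parameter set
#'
#' Checks structural legality (no probability on a forbidden state pair),
#' bounds, and row sums; then completes each row by assigning the residual
#' mass 1 - sum(outflows) to the row's residual state. The death row is fixed
#' to the absorbing identity.
#'
#' @param x `dfu_transitions` object (possibly incomplete).
#' @return The completed, validated `dfu_transitions` object.
#' @export
validate_transitions <- function(x) {
  if (!inherits(x, "dfu_transitions")) {
    stop("expected a 'dfu_transitions' object; see transition_parameters()")
  }
  states <- dfu_states()
  P <- x$matrix
  mask <- x$mask
  if (!identical(dim(P), c(6L, 6L))) stop("transition matrix must be 6 x 6")

  if (x$allow_perioperative_death && P["amputation", "death"] > 0) {
    warning("amputation -> death enabled: this departs from the printed ",
            "model structure (no perioperative mortality)")
  }

  bad <- which(!mask & P != 0, arr.ind = TRUE)
  if (nrow(bad)) {
    pair <- paste0(states[bad[1, 1]], " -> ", states[bad[1, 2]])
    stop("structural violation: transition ", pair, " is not allowed")
  }
  if (any(P < 0) || any(P > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }

  res <- residual_target()
  for (s in states) {
    # residual slot must not be user-supplied: it is derived
    out <- sum(P[s, ]) - P[s, res[[s]]]
    if (out > 1 + 1e-12) {
      stop("row sum exceeds 1 for state '", s, "': outflows total ",
           format(out, digits = 10))
    }
    P[s, res[[s]]] <- P[s, res[[s]]] + (1 - sum(P[s, ]))
  }
  P["death", ] <- 0
  P["death", "death"] <- 1

  rs <- rowSums(P)
  stopifnot(all(abs(rs - 1) < 1e-12))
  x$matrix <- P
  x$validated <- TRUE
  x
}

#' Apply an intervention's effect on ulcer recurrence
#'
#' Scales both recurrence transitions (post-DFU to non-severe and to severe
#' ulcer) by the effective relative risk
#' \deqn{rr_{eff} = compliance \cdot rr + (1 - compliance),}
#' i.e. compliant users experience the full relative risk `rr` while
#' non-compliant users experience standard-of-care risk. The freed
#' probability mass returns to the post-DFU self-transition; all other
#' entries are unchanged.
#'
#' @param params validated `dfu_transitions`.
#' @param rr relative risk of recurrence under the intervention, in (0, 1].
#' @param compliance proportion of the cohort using the intervention, in
#'   \[0, 1\].
#' @return A new validated `dfu_transitions` object.
#' @export
#' @examples
#' p <- placeholder_transitions()
#' p2 <- apply_intervention(p, rr = 0.9, compliance = 0.9)
#' p2$matrix["post_dfu", "nonsevere_dfu"] / p$matrix["post_dfu", "nonsevere_dfu"]
apply_intervention <- function(params, rr, compliance) {
  stopifnot(inherits(params, "dfu_transitions"), isTRUE(params$validated))
  if (!is.numeric(rr) || length(rr) != 1 || rr <= 0 || rr > 1) {
    stop("rr must be a single number in (0, 1]")
  }
  if (!is.numeric(compliance) || compliance < 0 || compliance > 1) {
    stop("compliance must lie in [0, 1]")
  }
  rr_eff <- compliance * rr + (1 - compliance)
  P <- params$matrix
  freed <- (1 - rr_eff) * (P["post_dfu", "nonsevere_dfu"] + P["post_dfu", "severe_dfu"])
  P["post_dfu", "nonsevere_dfu"] <- rr_eff * P["post_dfu", "nonsevere_dfu"]
  P["post_dfu", "severe_dfu"] <- rr_eff * P["post_dfu", "severe_dfu"]
  P["post_dfu", "post_dfu"] <- P["post_dfu", "post_dfu"] + freed
  params$matrix <- P
  validate_transitions(params)
}

#' Placeholder transition probabilities for demonstration and testing
#'
#' The published evaluation sourced its transition and mortality
#' probabilities from audit data and cited literature without printing the
#' values, so no faithful default can be shipped. This set is a PLACEHOLDER
#' with plausible orders of magnitude (monthly recurrence 0.02 split 70/30
#' non-severe/severe, modest healing and progression rates, low monthly
#' mortality). It exists so that examples and tests can run; any substantive
#' analysis must supply its own parameter file via [load_parameters()].
#'
#' @return Validated `dfu_transitions`.
#' @export
placeholder_transitions <- function() {
  transition_parameters(c(
    "post_dfu.to.nonsevere_dfu"   = 0.014,  # 70% of 0.02 monthly recurrence
    "post_dfu.to.severe_dfu"      = 0.006,  # 30% of 0.02
    "post_dfu.to.death"           = 0.003,
    "nonsevere_dfu.to.post_dfu"   = 0.25,
    "nonsevere_dfu.to.severe_dfu" = 0.05,
    "nonsevere_dfu.to.amputation" = 0.005,
    "severe_dfu.to.post_dfu"      = 0.12,
    "severe_dfu.to.amputation"    = 0.03,
    "severe_dfu.to.death"         = 0.01,
    "post_amputation.to.death"    = 0.008
  ))
}

#' @export
print.dfu_transitions <- function(x, digits = 4, ...) {
  cat("Monthly transition probabilities (6-state DFU model)\n")
  print(round(x$matrix, digits))
  invisible(x)
}
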