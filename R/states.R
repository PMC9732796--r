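#' Health states of the DFU recurrence model
#'
#' The model tracks a cohort of people with diabetes whose most recent foot
#' ulcer has healed. Six states are distinguished: `post_dfu` (healed, at risk
#' of recurrence), `nonsevere_dfu` (active ulcer, SINBAD score < 3),
#' `severe_dfu` (active ulcer, SINBAD score >= 3), `amputation` (undergoing an
#' amputation procedure and perioperative care; a one-cycle tunnel state),
#' `post_amputation` (long-term care after amputation), and `death`
#' (absorbing).
#'
#' @return Character vector of the six state names, in model order.
#' @export
#' @examples
#' dfu_states()
dfu_states <- function() {
  c("post_dfu", "nonsevere_dfu", "severe_dfu",
    "amputation", "post_amputation", "death")
}

#' Allowed-transition mask of the model structure
#'
#' Encodes which monthly moves are structurally possible:
#' * post-DFU: remain, develop a non-severe or severe ulcer, or die of
#'   unrelated causes;
#' * non-severe DFU: remain, heal back to post-DFU, progress to a severe
#'   ulcer, or progress to amputation;
#' * severe DFU: remain, heal back to post-DFU, progress to amputation, or
#'   die;
#' * amputation: move to post-amputation after one cycle (tunnel);
#' * post-amputation: remain or die;
#' * death: absorbing.
#'
#' Direct death from the non-severe-ulcer and amputation states is not part
#' of the printed structure. `allow_perioperative_death = TRUE` additionally
#' permits amputation -> death for users whose sources include perioperative
#' mortality; this departs from the default structure and is flagged with a
#' warning at parameter validation.
#'
#' @param allow_perioperative_death logical; permit amputation -> death.
#' @return 6 x 6 logical matrix, rows = from-state, cols = to-state.
#' @export
structural_mask <- function(allow_perioperative_death = FALSE) {
  s <- dfu_states()
  m <- matrix(FALSE, 6, 6, dimnames = list(s, s))
  m["post_dfu", c("post_dfu", "nonsevere_dfu", "severe_dfu", "death")] <- TRUE
  m["nonsevere_dfu", c("nonsevere_dfu", "post_dfu", "severe_dfu", "amputation")] <- TRUE
  m["severe_dfu", c("severe_dfu", "post_dfu", "amputation", "death")] <- TRUE
  m["amputation", "post_amputation"] <- TRUE
  if (isTRUE(allow_perioperative_death)) m["amputation", "death"] <- TRUE
  m["post_amputation", c("post_amputation", "death")] <- TRUE
  m["death", "death"] <- TRUE
  m
}

# Residual target per row: the state that absorbs 1 - sum(supplied outflows).
# Every state self-loops with the remainder except the amputation tunnel,
# which empties into post_amputation.
residual_target <- function() {
  c(post_dfu = "post_dfu", nonsevere_dfu = "nonsevere_dfu",
    severe_dfu = "severe_dfu", amputation = "post_amputation",
    post_amputation = "post_amputation", death = "death")
}
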