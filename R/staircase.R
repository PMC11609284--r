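# Adaptive SSD staircase: one-up one-down tracking toward 50% stopping.
# Constants from the study design: base 200 ms, step 50 ms, cap 750 ms.
# The design states no minimum; the floor defaults to 50 ms (one step above
# zero) so the delay stays positive.

#' Construct a staircase state
#'
#' @param ssdMs current SSD (ms); defaults to the base.
#' @param baseMs starting SSD for the first stop trial (ms).
#' @param stepMs step size (ms).
#' @param maxMs upper cap on the SSD (ms).
#' @param floorMs lower floor on the SSD (ms).
#' @param condition condition label this tracker belongs to.
#' @return a [StaircaseState-class]
#' @export
staircaseState <- function(ssdMs = baseMs, baseMs = 200, stepMs = 50,
                           maxMs = 750, floorMs = 50, condition = "none") {
  new("StaircaseState", ssdMs = ssdMs, baseMs = baseMs, stepMs = stepMs,
      maxMs = maxMs, floorMs = floorMs, condition = condition)
}

#' Update the staircase after a stop trial
#'
#' A correctly withheld response adds one step to the SSD (capped at
#' \code{maxMs}); a response on a stop trial subtracts one step (floored at
#' \code{floorMs}). All other fields are unchanged; trackers for different
#' conditions never interact.
#'
#' @param state a [StaircaseState-class].
#' @param respondedOnStop logical, whether the agent/participant responded.
#' @return the updated [StaircaseState-class]
#' @examples
#' updateStaircase(staircaseState(200), FALSE)  # withheld -> 250
#' @export
updateStaircase <- function(state, respondedOnStop) {
  stopifnot(is(state, "StaircaseState"), is.logical(respondedOnStop))
  newSsd <- if (respondedOnStop) {
    max(state@floorMs, state@ssdMs - state@stepMs)
  } else {
    min(state@maxMs, state@ssdMs + state@stepMs)
  }
  initialize(state, ssdMs = newSsd)
}
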