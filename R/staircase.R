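#' Transformed up-down staircase
#'
#' An n-down/1-up adaptive track on log10 contrast. Contrast moves one step
#' down after `rule` consecutive correct responses and one step up after any
#' error. The long-run convergence point is the `(1/2)^(1/rule)` percent-
#' correct level of the psychometric function: 70.7% for 2-down/1-up and
#' 84.1% for 4-down/1-up. The step size halves (from `step_init` to
#' `step_final`) after `reversal_switch` reversals.
#'
#' @param rule Number of consecutive corrects required to step down (2 or 4
#'   in the standard procedure).
#' @param start_contrast Starting RMS contrast.
#' @param step_init,step_final Step sizes in log10 contrast units.
#' @param reversal_switch Number of reversals after which the final step size
#'   is used.
#' @param max_trials Trials per staircase (75 in the standard procedure).
#' @param contrast_range Clamp on the tracked contrast.
#' @return Object of class `staircase`.
#' @export
staircase <- function(rule = 2, start_contrast, step_init = 0.1,
                      step_final = 0.05, reversal_switch = 2,
                      max_trials = 75, contrast_range = c(1e-4, 2)) {
  stopifnot(rule >= 1, start_contrast > 0, step_init > 0, step_final > 0)
  structure(list(rule = as.integer(rule),
                 log_contrast = log10(start_contrast),
                 step = step_init, step_final = step_final,
                 reversal_switch = reversal_switch,
                 reversals = 0L, run_correct = 0L,
                 trials_done = 0L, max_trials = as.integer(max_trials),
                 last_move = 0L, finished = FALSE,
                 log_range = log10(contrast_range)),
            class = "staircase")
}

#' Current contrast of a staircase
#' @param state A [staircase].
#' @return RMS contrast.
#' @export
staircase_contrast <- function(state) 10^state$log_contrast

#' Update a staircase with one trial outcome
#'
#' @param state A [staircase].
#' @param correct Logical, whether the response was correct.
#' @return The updated `staircase`; `finished` becomes `TRUE` after
#'   `max_trials` updates. Updating a finished staircase is an error.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase"), is.logical(correct))
  if (state$finished)
    stop("staircase already completed; no further updates allowed")
  state$trials_done <- state$trials_done + 1L
  move <- 0L
  if (correct) {
    state$run_correct <- state$run_correct + 1L
    if (state$run_correct >= state$rule) {
      move <- -1L
      state$run_correct <- 0L
    }
  } else {
    move <- 1L
    state$run_correct <- 0L
  }
  if (move != 0L) {
    if (state$last_move != 0L && move != state$last_move) {
      state$reversals <- state$reversals + 1L
      if (state$reversals >= state$reversal_switch)
        state$step <- state$step_final
    }
    state$last_move <- move
    state$log_contrast <- min(max(state$log_contrast + move * state$step,
                                  state$log_range[1]), state$log_range[2])
  }
  if (state$trials_done >= state$max_trials) state$finished <- TRUE
  state
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf("%d-down/1-up staircase: %d/%d trials, contrast %.4g, step %.3g log10, %d reversals%s\n",
              x$rule, x$trials_done, x$max_trials, staircase_contrast(x),
              x$step, x$reversals, if (x$finished) " (finished)" else ""))
  invisible(x)
}
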