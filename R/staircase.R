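#' Adaptive contrast staircase
#'
#' One independent staircase per spatial-frequency condition holds response
#' accuracy near 50%. Starting from 35% contrast with a 16% step, accuracy
#' over the last 10 trials of the just-tested condition is assessed after
#' every trial once 20 experimental trials have elapsed: above 50% correct
#' lowers that condition's contrast by one step, below 50% raises it, exactly
#' 50% leaves it. Every reversal in adjustment direction halves the step,
#' down to a minimum of 1%. Contrast is bounded to `[1, 100]`%.
#'
#' @param n_conditions Number of conditions (default 4).
#' @param initial_contrast Starting contrast in % (default 35).
#' @param initial_step Starting step in % (default 16).
#' @param min_step Step floor in % (default 1).
#' @return A `staircase_state`: per-condition `contrast`, `step`,
#'   `last_direction` (0 none, -1 down, +1 up).
#' @export
staircase_init <- function(n_conditions = 4, initial_contrast = 35,
                           initial_step = 16, min_step = 1) {
  structure(
    list(
      contrast = rep(initial_contrast, n_conditions),
      step = rep(initial_step, n_conditions),
      last_direction = rep(0L, n_conditions),
      min_step = min_step
    ),
    class = "staircase_state"
  )
}

#' @rdname staircase_init
#' @param state A `staircase_state`.
#' @param condition Condition index of the trial just completed.
#' @param recent_window Logical vector of correctness for the most recent
#'   trials of `condition` (the last 10 are used; no update with fewer than
#'   10).
#' @param trial_counter Number of experimental trials completed so far; no
#'   update before 20.
#' @export
staircase_update <- function(state, condition, recent_window, trial_counter) {
  if (trial_counter < 20) {
    return(state)
  }
  w <- utils::tail(recent_window, 10)
  if (length(w) < 10) {
    return(state)
  }
  acc <- mean(w)
  if (acc == 0.5) {
    return(state)
  }
  dir <- if (acc > 0.5) -1L else 1L # above target -> harder (lower contrast)
  state$contrast[condition] <- min(
    100,
    max(1, state$contrast[condition] + dir * state$step[condition])
  )
  # the adjustment that reverses direction still uses the current step; the
  # halving takes effect from the next adjustment on
  if (state$last_direction[condition] != 0L && dir != state$last_direction[condition]) {
    state$step[condition] <- max(state$min_step, state$step[condition] / 2)
  }
  state$last_direction[condition] <- dir
  state
}
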