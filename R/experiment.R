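#' Run the simulated 4AFC experiment for one participant
#'
#' Walks the trial schedule in order, drawing a fresh SNR sampling function
#' per trial, querying the synthetic observer at the staircase's current
#' contrast for the trial's condition, sampling a correct/error response, and
#' updating the staircase. Staircase state is carried across blocks and
#' sessions. The result is the trial log that all downstream analyses
#' consume.
#'
#' @param schedule A [build_trial_schedule()] tibble.
#' @param observer An [observer_model()].
#' @param seed Integer seed for this participant; per-trial SNR and response
#'   seeds are derived from it.
#' @param participant_id Identifier recorded in the log.
#' @param staircase Initial [staircase_init()] state.
#' @return A `trial_log` tibble: one row per trial with `participant_id`,
#'   `session`, `block`, `trial`, `condition`, `word`, `contrast`,
#'   `snr_seed`, `snr_values` (list-column of 24 floats), `correct`.
#'   Attribute `summary` holds the per-condition accuracy / mean-contrast
#'   table.
#' @export
run_simulated_experiment <- function(schedule, observer, seed = 1,
                                     participant_id = 1L,
                                     staircase = staircase_init()) {
  n <- nrow(schedule)
  n_cond <- length(staircase$contrast)
  cond <- schedule$condition
  contrast <- numeric(n)
  correct <- logical(n)
  snr_seed <- integer(n)
  snr_mat <- matrix(0, n, N_FRAMES)
  history <- vector("list", n_cond)
  for (c in seq_len(n_cond)) history[[c]] <- logical(0)
  resp_u <- with_seed_(derive_seed(seed, 1L), runif(n))

  for (i in seq_len(n)) {
    k <- cond[i]
    contrast[i] <- staircase$contrast[k]
    snr_seed[i] <- derive_seed(seed, 1000L + i)
    s <- generate_snr_function(snr_seed[i])
    snr_mat[i, ] <- as.numeric(s)
    p <- observer_p_correct(observer, k, s, contrast[i])
    correct[i] <- resp_u[i] < p
    history[[k]] <- c(history[[k]], correct[i])
    staircase <- staircase_update(staircase, k, history[[k]], i)
  }

  out <- tibble::tibble(
    participant_id = participant_id,
    session = schedule$session, block = schedule$block,
    trial = schedule$trial, condition = cond, word = schedule$word,
    contrast = contrast, snr_seed = snr_seed,
    snr_values = lapply(seq_len(n), function(i) snr_mat[i, ]),
    correct = correct
  )
  class(out) <- c("trial_log", class(out))
  attr(out, "summary") <- trial_log_summary(out)
  attr(out, "staircase_final") <- staircase
  out
}

#' Per-condition accuracy and contrast summary of a trial log
#'
#' @param log A `trial_log` tibble (one or more participants).
#' @param sessions Optional subset of sessions to summarize (e.g. the final
#'   two).
#' @return Tibble: `condition`, `n_trials`, `accuracy_pct`,
#'   `mean_contrast_pct`.
#' @export
trial_log_summary <- function(log, sessions = NULL) {
  if (!is.null(sessions)) log <- log[log$session %in% sessions, ]
  log |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy_pct = 100 * mean(.data$correct),
      mean_contrast_pct = mean(.data$contrast),
      .groups = "drop"
    )
}

#' Simulate a cohort of participants
#'
#' Builds one distractor map and per-participant randomized schedules from a
#' common word bank, then runs [run_simulated_experiment()] for each
#' participant with independent derived seeds.
#'
#' @param observer An [observer_model()].
#' @param n_participants Number of simulated participants (default 16).
#' @param words Word bank (character); default is a synthetic 400-word bank.
#' @param n_sessions,blocks_per_session,trials_per_block Schedule geometry.
#' @param seed Master seed.
#' @param px_per_deg Rendering resolution for the distractor similarity step.
#' @return A `trial_log` tibble covering all participants.
#' @export
simulate_cohort <- function(observer, n_participants = 16,
                            words = make_word_bank(400, seed = seed),
                            n_sessions = 4, blocks_per_session = 4,
                            trials_per_block = 200, seed = 1,
                            px_per_deg = 8) {
  bank <- lapply(words, render_word_image, px_per_deg = px_per_deg)
  names(bank) <- words
  dm <- select_distractors(bank, seed = derive_seed(seed, 31L))
  logs <- purrr::map(seq_len(n_participants), function(p) {
    sched <- build_trial_schedule(words,
      n_sessions = n_sessions,
      blocks_per_session = blocks_per_session,
      trials_per_block = trials_per_block,
      distractor_map = dm, seed = derive_seed(seed, 500L + p)
    )
    run_simulated_experiment(sched, observer,
      seed = derive_seed(seed, 900L + p), participant_id = p
    )
  })
  out <- dplyr::bind_rows(logs)
  class(out) <- c("trial_log", class(out))
  attr(out, "summary") <- trial_log_summary(out)
  out
}
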