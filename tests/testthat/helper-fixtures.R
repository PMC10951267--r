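# Shared fixtures, built once per test run.

# A trivially valid distractor map (rotations of the word list); similarity
# is irrelevant for schedule/experiment tests.
rotation_distractor_map <- function(words) {
  n <- length(words)
  rot <- function(k) words[(seq_len(n) + k - 1) %% n + 1]
  tibble::tibble(
    target = words, distractor_1 = rot(2), distractor_2 = rot(3),
    distractor_3 = rot(4), summed_similarity = 0
  )
}

# A hand-built trial log slice with known SNR rows and labels.
toy_trial_log <- function(snr_rows, correct, participant = 1L, condition = 1L) {
  tibble::tibble(
    participant_id = participant, session = 1L, block = 1L,
    trial = seq_along(correct), condition = condition, word = "babab",
    contrast = 35, snr_seed = seq_along(correct),
    snr_values = snr_rows, correct = correct
  )
}

random_snr_rows <- function(n, seed0 = 1) {
  lapply(seq_len(n), function(i) as.numeric(generate_snr_function(seed0 + i)))
}

# Reduced-geometry cohort used by the staircase and classification
# acceptance tests: 16 participants, 100 words, 4 sessions x 4 blocks x 50
# trials (800 trials each, 200 per condition). Memoized across test files.
cohort_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$trials)) {
      obs <- make_paperlike_observer(seed = 1)
      cache$observer <- obs
      cache$trials <- simulate_cohort(obs,
        n_participants = 16,
        words = make_word_bank(100, seed = 1),
        trials_per_block = 50, seed = 9
      )
    }
    list(observer = cache$observer, trials = cache$trials)
  }
})
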