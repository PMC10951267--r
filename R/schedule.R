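#' Build the randomized trial schedule
#'
#' Every word is presented eight times over the experiment, exactly twice in
#' each of the four spatial-frequency conditions, with no word repeated
#' within a block. At the defaults (400 words, 4 sessions x 4 blocks x 200
#' trials) this yields 3200 trials. The builder distributes each word's eight
#' presentations over eight distinct blocks, filling the fullest blocks
#' first, which always succeeds when the trial budget matches the word
#' budget and the block size does not exceed the number of words.
#'
#' @param words Character vector of target words; `8 * length(words)` must
#'   equal the total trial count.
#' @param n_sessions,blocks_per_session,trials_per_block Schedule geometry
#'   (defaults 4, 4, 200).
#' @param distractor_map A [select_distractors()] result covering all words.
#' @param seed Integer seed randomizing block assignment and trial order.
#' @param n_conditions Number of spatial-frequency conditions (default 4);
#'   presentations per word is `2 * n_conditions`.
#' @return A tibble (`trial_schedule`): `session`, `block`, `trial`,
#'   `trial_global`, `word`, `condition`, `distractor_1..3`.
#' @export
#' @examples
#' words <- make_word_bank(8)
#' dm <- tibble::tibble(
#'   target = words, distractor_1 = words[c(2:8, 1)],
#'   distractor_2 = words[c(3:8, 1:2)], distractor_3 = words[c(4:8, 1:3)],
#'   summed_similarity = 0
#' )
#' sched <- build_trial_schedule(words,
#'   n_sessions = 1, blocks_per_session = 8,
#'   trials_per_block = 8, distractor_map = dm, seed = 1
#' )
build_trial_schedule <- function(words, n_sessions = 4, blocks_per_session = 4,
                                 trials_per_block = 200, distractor_map, seed = 1,
                                 n_conditions = 4) {
  n_words <- length(words)
  n_blocks <- n_sessions * blocks_per_session
  total <- n_blocks * trials_per_block
  per_word <- 2L * n_conditions
  if (n_words * per_word != total) {
    abort(sprintf(
      "word budget (%d words x %d presentations = %d) does not match trial budget (%d)",
      n_words, per_word, n_words * per_word, total
    ))
  }
  if (trials_per_block > n_words) {
    abort(sprintf(
      "block size %d exceeds %d distinct words: within-block repeats unavoidable",
      trials_per_block, n_words
    ))
  }
  if (n_blocks < per_word) {
    abort(sprintf(
      "%d blocks cannot host %d presentations of a word without within-block repeats",
      n_blocks, per_word
    ))
  }
  if (!all(words %in% distractor_map$target)) {
    abort("distractor_map does not cover all words")
  }

  with_seed_(derive_seed(seed, 21L), {
    # Assign each word's presentations to distinct blocks, always taking the
    # blocks with the most remaining capacity (ties broken at random). This
    # greedy choice keeps capacities balanced and never strands a word.
    capacity <- rep(trials_per_block, n_blocks)
    block_of <- matrix(0L, n_words, per_word)
    for (i in sample.int(n_words)) {
      pick <- order(capacity + runif(n_blocks), decreasing = TRUE)[seq_len(per_word)]
      if (any(capacity[pick] <= 0)) {
        abort("schedule construction failed: block capacity exhausted")
      }
      block_of[i, ] <- pick
      capacity[pick] <- capacity[pick] - 1L
    }
    # Conditions: each word gets each condition exactly twice, shuffled over
    # its eight block slots.
    cond_of <- t(vapply(
      seq_len(n_words),
      function(i) sample(rep(seq_len(n_conditions), 2L)),
      integer(per_word)
    ))

    long <- tibble::tibble(
      word = rep(words, each = per_word),
      block_id = as.integer(t(block_of)),
      condition = as.integer(t(cond_of))
    )
    long <- long[order(long$block_id, runif(nrow(long))), ]
  })

  long$session <- (long$block_id - 1L) %/% blocks_per_session + 1L
  long$block <- (long$block_id - 1L) %% blocks_per_session + 1L
  long$trial <- stats::ave(seq_len(nrow(long)), long$block_id, FUN = seq_along)
  long$trial_global <- seq_len(nrow(long))
  dm <- distractor_map[match(long$word, distractor_map$target), ]
  out <- tibble::tibble(
    session = long$session, block = long$block, trial = as.integer(long$trial),
    trial_global = long$trial_global, word = long$word,
    condition = long$condition,
    distractor_1 = dm$distractor_1, distractor_2 = dm$distractor_2,
    distractor_3 = dm$distractor_3
  )
  class(out) <- c("trial_schedule", class(out))
  out
}

#' Check every schedule invariant exhaustively
#'
#' @param schedule A [build_trial_schedule()] result.
#' @param n_conditions Number of conditions expected (default 4).
#' @return A tibble with one row per invariant (`check`, `ok`); attribute
#'   `valid` is `TRUE` iff all hold.
#' @export
validate_trial_schedule <- function(schedule, n_conditions = 4) {
  per_word <- 2L * n_conditions
  by_word <- table(schedule$word)
  by_word_cond <- table(schedule$word, schedule$condition)
  block_key <- paste(schedule$session, schedule$block)
  no_repeat <- !any(vapply(
    split(schedule$word, block_key),
    function(w) anyDuplicated(w) > 0, logical(1)
  ))
  checks <- tibble::tibble(
    check = c(
      "each word presented 2 x n_conditions times",
      "each word twice per condition",
      "no word repeated within a block",
      "no target among its own distractors",
      "equal block sizes"
    ),
    ok = c(
      all(by_word == per_word),
      all(by_word_cond == 2L),
      no_repeat,
      !any(schedule$word == schedule$distractor_1 |
        schedule$word == schedule$distractor_2 |
        schedule$word == schedule$distractor_3),
      length(unique(table(block_key))) == 1
    )
  )
  attr(checks, "valid") <- all(checks$ok)
  checks
}
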