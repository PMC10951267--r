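TRIAL_LOG_COLUMNS <- c(
  "participant_id", "session", "block", "trial", "condition", "word",
  "contrast", "snr_seed", "snr_values", "correct"
)

#' Write / read a trial log as CSV
#'
#' One row per trial with a header. The 24 SNR values of a trial are
#' serialized as semicolon-separated floats in the single `snr_values`
#' column (full shortest-round-trip precision), so the file round-trips
#' bit-exactly on text: write, read, write again gives identical bytes.
#'
#' @param log A `trial_log` tibble.
#' @param path CSV file path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns the `trial_log` tibble.
#' @export
write_trial_log <- function(log, path) {
  out <- log[, setdiff(TRIAL_LOG_COLUMNS, "snr_values")]
  out$snr_values <- vapply(
    log$snr_values,
    function(v) paste(vapply(v, format_num, character(1)), collapse = ";"),
    character(1)
  )
  out <- out[, TRIAL_LOG_COLUMNS]
  readr::write_csv(out, path)
  invisible(path)
}

format_num <- function(x) {
  s <- format(x, digits = 15)
  if (as.numeric(s) != x) s <- format(x, digits = 17)
  s
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      participant_id = readr::col_integer(), session = readr::col_integer(),
      block = readr::col_integer(), trial = readr::col_integer(),
      condition = readr::col_integer(), word = readr::col_character(),
      contrast = readr::col_double(), snr_seed = readr::col_integer(),
      snr_values = readr::col_character(), correct = readr::col_logical()
    )
  )
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(raw))
  if (length(missing)) {
    abort(paste0("trial log is missing columns: ", paste(missing, collapse = ", ")))
  }
  parsed <- lapply(seq_len(nrow(raw)), function(i) {
    v <- as.numeric(strsplit(raw$snr_values[i], ";", fixed = TRUE)[[1]])
    if (length(v) != N_FRAMES || anyNA(v)) {
      abort(sprintf("row %d: snr_values must hold %d floats, found %d", i, N_FRAMES, length(v)))
    }
    v
  })
  raw$snr_values <- parsed
  class(raw) <- c("trial_log", class(raw))
  attr(raw, "summary") <- trial_log_summary(raw)
  raw
}

#' Export a set of CIs as a flat CSV
#'
#' One row per cell: `participant_id`, `condition`, `domain`, `freq_hz`,
#' `frame`, `time_ms`, `z`.
#'
#' @param ci_set A `ci_set` (or single `zci` in a list).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_ci_csv <- function(ci_set, path) {
  readr::write_csv(tidy.ci_set(ci_set), path)
  invisible(path)
}

# Run configuration -------------------------------------------------------

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the simulation and analysis chain
#' with the paradigm's defaults, and serializes losslessly to JSON. The
#' `demo` preset scales the cohort down (8 participants, 100 words, 800
#' trials each) for a quick complete run.
#'
#' @param ... Named overrides of the defaults.
#' @param preset `"full"` (the paradigm's geometry) or `"demo"`.
#' @return A `run_config` list.
#' @export
run_config <- function(..., preset = c("full", "demo")) {
  preset <- match.arg(preset)
  cfg <- list(
    schema_version = 1L,
    seed = 1L,
    n_participants = 16L,
    n_words = 400L,
    n_sessions = 4L,
    blocks_per_session = 4L,
    trials_per_block = 200L,
    frame_rate = FRAME_RATE_HZ,
    duration_ms = 200,
    snr_freqs = SNR_FREQS_HZ,
    snr_max = SNR_MAX,
    filter_order = 2L,
    px_per_deg = 32L,
    similarity_px_per_deg = 8L,
    noise = "uniform",
    initial_contrast = 35,
    initial_step = 16,
    min_step = 1,
    observer_slope = 24,
    observer_criterion = 0.33,
    observer_lapse = 0,
    n_boot = 1000L,
    n_perm = 500L,
    alpha = 0.05,
    fwhm_time_ms = 19.6,
    fwhm_tf_time_ms = 29.3,
    fwhm_tf_freq_hz = 17.7,
    svm_cost = 1,
    stop_accuracy = 90,
    max_steps = 200L
  )
  if (preset == "demo") {
    cfg$n_participants <- 8L
    cfg$n_words <- 100L
    cfg$trials_per_block <- 50L
    cfg$n_boot <- 300L
    cfg$n_perm <- 200L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown config fields: ", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

# Pipeline ----------------------------------------------------------------

#' Run the full simulation -> CI -> classification pipeline
#'
#' Drives the whole chain from one configuration: simulate the cohort, write
#' the trial log and the per-condition accuracy/contrast summary, compute
#' individual z-scored CIs in both domains, average, smooth and threshold
#' the group CIs per condition with the Pixel test, classify individual CIs
#' in all four feature representations, and compute the condition signatures
#' of the best representation. All outputs are deterministic given the
#' config (stage seeds derive from `config$seed`); stage timings go to
#' `message()` only.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results; files are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config = run_config(preset = "demo"), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    message(sprintf("[%s] %.1f s", name, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  observer <- make_paperlike_observer(
    seed = config$seed, slope = config$observer_slope,
    criterion = config$observer_criterion, lapse = config$observer_lapse
  )
  write_observer_json(observer, file.path(out_dir, "observer.json"))
  write_config(config, file.path(out_dir, "config.json"))

  trials <- stage("simulate", simulate_cohort(
    observer,
    n_participants = config$n_participants,
    words = make_word_bank(config$n_words, seed = config$seed),
    n_sessions = config$n_sessions,
    blocks_per_session = config$blocks_per_session,
    trials_per_block = config$trials_per_block,
    seed = config$seed, px_per_deg = config$similarity_px_per_deg
  ))
  write_trial_log(trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(trial_log_summary(trials), file.path(out_dir, "summary_by_condition.csv"))

  cis <- stage("ci", {
    list(
      time = compute_individual_cis(trials, "time",
        n_boot = config$n_boot, seed = derive_seed(config$seed, 2L)
      ),
      tf = compute_individual_cis(trials, "time_frequency",
        n_boot = config$n_boot, seed = derive_seed(config$seed, 3L)
      )
    )
  })
  write_ci_csv(cis$time, file.path(out_dir, "ci_time.csv"))
  write_ci_csv(cis$tf, file.path(out_dir, "ci_tf.csv"))

  pixel <- stage("pixel_test", {
    conds <- sort(unique(trials$condition))
    purrr::map(conds, function(cc) {
      purrr::map(cis, function(set) {
        sub <- set[vapply(set, function(z) z$condition[1] == cc, logical(1))]
        gz <- smooth_ci(average_cis(sub),
          fwhm_time_ms = if (attr(set, "domain") == "time") config$fwhm_time_ms else config$fwhm_tf_time_ms,
          fwhm_freq_hz = config$fwhm_tf_freq_hz
        )
        pt <- pixel_test(gz, sub, trials,
          n_perm = config$n_perm,
          alpha = config$alpha, seed = derive_seed(config$seed, 4L + cc)
        )
        list(group_z = gz, pixel = pt)
      })
    }) |> stats::setNames(paste0("condition_", conds))
  })
  sig_tbl <- purrr::imap_dfr(pixel, function(doms, cname) {
    purrr::imap_dfr(doms, function(r, dname) {
      dplyr::mutate(tidy.zci(r$group_z),
        significant = as.logical(r$pixel$significance_mask),
        z_threshold = r$pixel$z_threshold_high,
        condition_label = cname, domain_label = dname
      )
    })
  })
  readr::write_csv(sig_tbl, file.path(out_dir, "group_ci_significance.csv"))

  classify <- stage("classify", {
    reps <- c("time", "time_fourier", "tf", "tf_fourier")
    res <- purrr::map(reps, function(r) {
      set <- if (r %in% c("time", "time_fourier")) cis$time else cis$tf
      tryCatch(
        stepwise_svm_loo(featureize(set, r),
          stop_accuracy = config$stop_accuracy,
          max_steps = config$max_steps, cost = config$svm_cost
        ),
        error = function(e) list(error = conditionMessage(e))
      )
    })
    stats::setNames(res, reps)
  })

  signatures <- NULL
  ok <- vapply(classify, inherits, logical(1), "classifier_result")
  if (any(ok)) {
    accs <- vapply(classify[ok], `[[`, numeric(1), "best_accuracy")
    best_rep <- names(accs)[which.max(accs)]
    set <- if (best_rep %in% c("time", "time_fourier")) cis$time else cis$tf
    fm <- featureize(set, best_rep)
    signatures <- condition_signature(fm, classify[[best_rep]]$selected_features)
    readr::write_csv(signatures, file.path(out_dir, "signatures.csv"))
  }

  report <- list(
    schema_version = 1L,
    seed = config$seed,
    summary_by_condition = trial_log_summary(trials),
    classification = purrr::map(classify, function(r) {
      if (inherits(r, "classifier_result")) glance.classifier_result(r) else r
    })
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows"
  )
  invisible(list(
    trials = trials, cis = cis, pixel = pixel,
    classification = classify, signatures = signatures
  ))
}
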