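#' Draw inter-trial jitter values
#'
#' Samples jitter durations from a discrete pseudo-exponential
#' distribution.
#'
#' @param n Number of draws.
#' @param levels Two-column matrix (seconds, probability); defaults to
#'   [default_jitter_levels()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` jitter durations in seconds.
#' @export
draw_jitter <- function(n, levels = default_jitter_levels(), seed = NULL) {
  levels <- as.matrix(levels)
  if (abs(sum(levels[, 2]) - 1) > 1e-12)
    stop("draw_jitter: probabilities must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  sample(levels[, 1], size = n, replace = TRUE, prob = levels[, 2])
}

#' Generate the event schedule for one run
#'
#' Lays out one run of the event-related design: every word of the pool
#' appears exactly once in randomized order, and zero to
#' `max_catch_per_run` catch trials showing number words are inserted at
#' random positions. Each trial starts with a fixation cross, a blank, the
#' word, a post-word delay, and an inter-trial interval jittered according
#' to the configured pseudo-exponential distribution, so successive word
#' onsets are `fixation_s + blank1_s + blank2_s + jitter` apart. Onsets are
#' seconds from the first retained (post-discard) volume.
#'
#' @param config A [sim_config()].
#' @param run_index 0-based run index (selects the run's condition).
#' @param seed Optional integer seed.
#' @param max_retries Jittered schedules are rejection-sampled: a drawn
#'   schedule whose last trial does not complete within the usable scan
#'   time is redrawn, up to `max_retries` times, before a configuration
#'   error is signalled (a design that cannot fit fails every draw).
#' @return An `event_table`: data.frame with columns onset, duration, word,
#'   category, condition, run_id, is_catch.
#' @export
generate_schedule <- function(config, run_index, seed = NULL,
                              max_retries = 25L) {
  stopifnot(inherits(config, "sim_config"))
  run_index <- as.integer(run_index)
  if (run_index < 0L || run_index >= config$n_runs)
    stop("generate_schedule: 'run_index' must be in [0, n_runs)")
  if (!is.null(seed)) set.seed(seed)

  usable <- (config$volumes_per_run - config$n_discard) * config$tr
  run_id <- sprintf("run%02d", run_index + 1L)
  base_words <- c(config$word_pool$living, config$word_pool$nonliving)
  base_cats <- rep(c("living", "nonliving"),
                   each = config$n_words_per_category)

  for (attempt in seq_len(max_retries + 1L)) {
    ord <- sample.int(length(base_words))
    words <- base_words[ord]
    categories <- base_cats[ord]

    n_catch <- sample.int(config$max_catch_per_run + 1L, 1L) - 1L
    if (n_catch > 0L) {
      catch_words <- sample(catch_word_pool(), n_catch, replace = TRUE)
      pos <- sort(sample.int(length(words) + 1L, n_catch))
      for (k in seq_len(n_catch)) {
        at <- pos[k] + k - 1L
        words <- append(words, catch_words[k], after = at - 1L)
        categories <- append(categories, NA_character_, after = at - 1L)
      }
    }
    is_catch <- is.na(categories)

    n_trials <- length(words)
    spacing <- config$fixation_s + config$blank1_s + config$blank2_s +
      draw_jitter(n_trials - 1L, config$jitter_levels)
    onset0 <- config$fixation_s + config$blank1_s
    onsets <- onset0 + c(0, cumsum(spacing))
    if (onsets[n_trials] + config$word_s + config$blank2_s <= usable)
      break
    if (attempt > max_retries)
      stop(sprintf(
        "generate_schedule: schedule for %s exceeds the run duration (%.2f s)",
        run_id, usable))
  }

  ev <- data.frame(
    onset = onsets,
    duration = rep(config$word_s, n_trials),
    word = words,
    category = categories,
    condition = rep(config$condition_order[run_index + 1L], n_trials),
    run_id = rep(run_id, n_trials),
    is_catch = is_catch,
    stringsAsFactors = FALSE
  )
  as_event_table(ev)
}

#' Event table constructor / validator
#'
#' Validates and classes a data.frame of trial events. Onsets are seconds
#' from the start of the (post-discard) run grid and must be strictly
#' increasing within each run; every non-catch word must map to a single
#' category.
#'
#' @param x data.frame with columns onset, duration, word, category,
#'   condition, run_id, is_catch.
#' @return `x` with class `event_table` prepended.
#' @export
as_event_table <- function(x) {
  needed <- c("onset", "duration", "word", "category", "condition",
              "run_id", "is_catch")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("as_event_table: missing columns: ", paste(miss, collapse = ", "))
  for (r in unique(x$run_id)) {
    o <- x$onset[x$run_id == r]
    if (any(diff(o) <= 0))
      stop("as_event_table: onsets must be strictly increasing within run '",
           r, "'")
  }
  wc <- unique(x[!x$is_catch, c("word", "category")])
  if (anyDuplicated(wc$word))
    stop("as_event_table: a word maps to more than one category")
  class(x) <- c("event_table", "data.frame")
  x
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d trials (%d catch) in %d run(s)\n",
              nrow(x), sum(x$is_catch), length(unique(x$run_id))))
  NextMethod()
}
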