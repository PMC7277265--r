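#' Default word pool
#'
#' The 18 living (animal) and 18 non-living (tool) Spanish words of the
#' event-related design, as used by the default simulation configuration.
#'
#' @return Named list with character vectors `living` and `nonliving`,
#'   18 words each.
#' @export
default_word_pool <- function() {
  list(
    living = c(
      "tigre", "gallo", "perro", "oveja", "cerdo", "gorila", "burro",
      "yegua", "ardilla", "conejo", "gallina", "caballo", "ballena",
      "tortuga", "pantera", "camello", "elefante", "canguro"
    ),
    nonliving = c(
      "llave", "lapiz", "tijera", "aguja", "pinza", "sierra", "clavo",
      "pincel", "alicate", "tuerca", "navaja", "cepillo", "taladro",
      "soplete", "tornillo", "cuchara", "martillo", "cuchillo"
    )
  )
}

# number words shown on catch trials
catch_word_pool <- function() c("cero", "uno", "tres")

#' Region-of-interest specification for the simulator
#'
#' Describes one simulated ROI: its size and the amplitudes of the signal
#' components planted in it. Category patterns are multiplied by a
#' condition-dependent gain (`category_gain_deep` in deep-processing runs,
#' `category_gain_shallow` in shallow runs); word patterns are word-specific
#' deviations shared across conditions. All amplitudes are in units of the
#' noise standard deviation scale of the BOLD signal.
#'
#' @param name ROI label.
#' @param n_voxels Number of voxels (>= 2).
#' @param category_gain_deep Category-pattern amplitude in deep runs (>= 0).
#' @param category_gain_shallow Category-pattern amplitude in shallow runs
#'   (>= 0).
#' @param word_gain Word-specific pattern amplitude (>= 0).
#' @param noise_sd Standard deviation of the white Gaussian noise (> 0).
#' @param drift_amplitude Amplitude of the low-frequency drift (>= 0).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, n_voxels = 50, category_gain_deep = 1,
                     category_gain_shallow = 0.3, word_gain = 0.5,
                     noise_sd = 1, drift_amplitude = 0.5) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_voxels <- as.integer(n_voxels)
  if (is.na(n_voxels) || n_voxels < 2L)
    stop("roi_spec: 'n_voxels' must be >= 2 for ROI '", name, "'")
  gains <- c(category_gain_deep = category_gain_deep,
             category_gain_shallow = category_gain_shallow,
             word_gain = word_gain, drift_amplitude = drift_amplitude)
  if (any(!is.finite(gains)) || any(gains < 0))
    stop("roi_spec: gains and drift amplitude must be finite and >= 0")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("roi_spec: 'noise_sd' must be > 0")
  structure(
    list(name = name, n_voxels = n_voxels,
         category_gain_deep = category_gain_deep,
         category_gain_shallow = category_gain_shallow,
         word_gain = word_gain, noise_sd = noise_sd,
         drift_amplitude = drift_amplitude),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf(
    "ROI '%s': %d voxels; gains deep=%.3g shallow=%.3g word=%.3g; noise sd=%.3g\n",
    x$name, x$n_voxels, x$category_gain_deep, x$category_gain_shallow,
    x$word_gain, x$noise_sd))
  invisible(x)
}

#' Simulation configuration for the event-related design
#'
#' Collects every parameter of the synthetic dataset: the trial design
#' (runs, trials, timing, pseudo-exponential inter-trial jitter, catch
#' trials), the scanner grid (TR, volumes per run, discarded volumes), the
#' ROIs and their planted signal amplitudes, and the cross-ROI coupling of
#' the trial-to-trial signal gain ("gating") that informational-connectivity
#' analysis is designed to detect.
#'
#' Successive word onsets are separated by
#' `fixation_s + blank1_s + blank2_s + jitter`, i.e. 10.75 to 12.75 s under
#' the defaults, the word display overlapping the start of the post-word
#' delay. Jitter levels default to the pseudo-exponential distribution
#' 6 s (50%), 6.5 s (25%), 7 s (12.5%), 7.5 s (6.25%), 8 s (6.25%).
#'
#' @param n_runs Number of runs (default 8).
#' @param trials_per_run Word trials per run; must equal
#'   `2 * n_words_per_category`.
#' @param n_words_per_category Words per category (default 18).
#' @param tr Repetition time in seconds (default 0.85).
#' @param volumes_per_run Volumes acquired per run (default 520).
#' @param n_discard Leading volumes discarded for steady-state
#'   magnetization (default 9).
#' @param fixation_s,blank1_s,word_s,blank2_s Trial component durations in
#'   seconds (defaults 0.25, 0.5, 1, 4).
#' @param jitter_levels Two-column matrix or data.frame of
#'   (seconds, probability); probabilities must sum to 1.
#' @param max_catch_per_run Maximum number of inserted catch trials per run
#'   (default 2).
#' @param condition_order Character vector, one of "deep"/"shallow" per run
#'   with equal counts; default alternates starting with "deep".
#' @param roi_specs List of [roi_spec()] objects; default one 50-voxel ROI.
#' @param coupling Optional list of couplings, each a list/vector
#'   `(roi_a, roi_b, strength)` with strength in [0, 1] and an optional
#'   fourth element `condition` in "both"/"deep"/"shallow" (default "both")
#'   restricting the coupling to runs of one condition.
#' @param word_pool Named list with `living` and `nonliving` word vectors.
#' @param baseline Baseline BOLD intensity (arbitrary units, default 100).
#' @param seed Default integer seed for dataset generation.
#' @return An object of class `sim_config`.
#' @seealso [generate_schedule()], [generate_dataset()]
#' @export
sim_config <- function(n_runs = 8, trials_per_run = 36,
                       n_words_per_category = 18, tr = 0.85,
                       volumes_per_run = 520, n_discard = 9,
                       fixation_s = 0.25, blank1_s = 0.5, word_s = 1,
                       blank2_s = 4,
                       jitter_levels = default_jitter_levels(),
                       max_catch_per_run = 2, condition_order = NULL,
                       roi_specs = list(roi_spec("roi1")),
                       coupling = list(),
                       word_pool = NULL, baseline = 100, seed = 1L) {
  n_runs <- as.integer(n_runs)
  trials_per_run <- as.integer(trials_per_run)
  n_words_per_category <- as.integer(n_words_per_category)
  if (trials_per_run != 2L * n_words_per_category)
    stop("sim_config: 'trials_per_run' must equal 2 * n_words_per_category")
  durs <- c(tr = tr, fixation_s = fixation_s, blank1_s = blank1_s,
            word_s = word_s, blank2_s = blank2_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("sim_config: all durations must be positive")
  jitter_levels <- as.matrix(jitter_levels)
  if (ncol(jitter_levels) != 2L)
    stop("sim_config: 'jitter_levels' needs columns (seconds, probability)")
  colnames(jitter_levels) <- c("seconds", "probability")
  if (abs(sum(jitter_levels[, "probability"]) - 1) > 1e-12)
    stop("sim_config: jitter probabilities must sum to 1")
  if (any(jitter_levels[, "seconds"] <= 0))
    stop("sim_config: jitter durations must be positive")
  if (is.null(condition_order))
    condition_order <- rep(c("deep", "shallow"), length.out = n_runs)
  condition_order <- match.arg(condition_order, c("deep", "shallow"),
                               several.ok = TRUE)
  if (length(condition_order) != n_runs)
    stop("sim_config: 'condition_order' must have one entry per run")
  if (sum(condition_order == "deep") != sum(condition_order == "shallow"))
    stop("sim_config: conditions must appear equally often across runs")
  if (is.null(word_pool)) {
    pool <- default_word_pool()
    word_pool <- list(living = pool$living[seq_len(n_words_per_category)],
                      nonliving = pool$nonliving[seq_len(n_words_per_category)])
  }
  if (length(word_pool$living) != n_words_per_category ||
      length(word_pool$nonliving) != n_words_per_category)
    stop("sim_config: word pool must have 'n_words_per_category' words per category")
  words <- c(word_pool$living, word_pool$nonliving)
  if (anyDuplicated(words))
    stop("sim_config: word pool labels must be distinct")
  if (!all(vapply(roi_specs, inherits, logical(1), "roi_spec")))
    stop("sim_config: 'roi_specs' must be a list of roi_spec objects")
  roi_names <- vapply(roi_specs, `[[`, character(1), "name")
  if (anyDuplicated(roi_names)) stop("sim_config: duplicate ROI names")
  names(roi_specs) <- roi_names
  coupling <- lapply(coupling, function(cp) {
    cp <- as.list(cp)
    if (length(cp) == 3L) cp <- c(cp, list("both"))
    names(cp) <- c("roi_a", "roi_b", "strength", "condition")
    cp$strength <- as.numeric(cp$strength)
    cp$condition <- match.arg(cp$condition, c("both", "deep", "shallow"))
    if (!all(c(cp$roi_a, cp$roi_b) %in% roi_names))
      stop("sim_config: coupling references unknown ROI '",
           setdiff(c(cp$roi_a, cp$roi_b), roi_names)[1], "'")
    if (cp$roi_a == cp$roi_b)
      stop("sim_config: coupling must join two distinct ROIs")
    if (!is.finite(cp$strength) || cp$strength < 0 || cp$strength > 1)
      stop("sim_config: coupling strength must lie in [0, 1]")
    cp
  })
  structure(
    list(n_runs = n_runs, trials_per_run = trials_per_run,
         n_words_per_category = n_words_per_category, tr = tr,
         volumes_per_run = as.integer(volumes_per_run),
         n_discard = as.integer(n_discard), fixation_s = fixation_s,
         blank1_s = blank1_s, word_s = word_s, blank2_s = blank2_s,
         jitter_levels = jitter_levels,
         max_catch_per_run = as.integer(max_catch_per_run),
         condition_order = condition_order, roi_specs = roi_specs,
         coupling = coupling, word_pool = word_pool, baseline = baseline,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default pseudo-exponential jitter levels
#'
#' Inter-trial jitter between 6 and 8 s in 0.5 s steps with halving
#' probabilities: 50%, 25%, 12.5%, and the residual 12.5% split equally
#' over 7.5 and 8 s so the probabilities sum to one.
#'
#' @return Two-column matrix (seconds, probability).
#' @export
default_jitter_levels <- function() {
  cbind(seconds = c(6, 6.5, 7, 7.5, 8),
        probability = c(0.5, 0.25, 0.125, 0.0625, 0.0625))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d runs x %d trials (%d words/category)\n",
              x$n_runs, x$trials_per_run, x$n_words_per_category))
  cat(sprintf("  TR %.3g s, %d volumes/run (%d discarded)\n",
              x$tr, x$volumes_per_run, x$n_discard))
  cat(sprintf("  conditions: %s\n", paste(x$condition_order, collapse = " ")))
  cat(sprintf("  ROIs: %s\n", paste(names(x$roi_specs), collapse = ", ")))
  if (length(x$coupling))
    for (cp in x$coupling)
      cat(sprintf("  coupling %s~%s strength %.2f (%s)\n",
                  cp$roi_a, cp$roi_b, cp$strength, cp$condition))
  invisible(x)
}
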