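#' Drop discarded leading volumes from a run
#'
#' @param run A [bold_run()].
#' @return The run with its first `n_discarded` volumes removed and
#'   `n_discarded` reset to 0.
#' @export
discard_volumes <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  if (run$n_discarded > 0L) {
    run$data <- run$data[, -seq_len(run$n_discarded), drop = FALSE]
    run$n_discarded <- 0L
  }
  run
}

#' Remove invariant voxels from one run
#'
#' Voxels whose value does not vary over the run cause numerical trouble
#' in z-scoring and are removed before normalization.
#'
#' @param run A [bold_run()].
#' @return List with `run` (voxel-subset [bold_run()]) and `kept` (integer
#'   indices of retained voxels in the original ordering).
#' @export
remove_invariant_voxels <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  if (nrow(run$data) == 0L) stop("remove_invariant_voxels: empty run")
  v <- apply(run$data, 1L, stats::var)
  kept <- which(v > 0)
  if (length(kept) == 0L)
    stop("remove_invariant_voxels: all voxels invariant in run '",
         run$run_id, "' (empty ROI)")
  run$data <- run$data[kept, , drop = FALSE]
  list(run = run, kept = kept)
}

#' Remove invariant voxels consistently across the runs of one ROI
#'
#' A voxel is dropped from every run if it is invariant within any single
#' run (`scope = "per_run"`, the default) or only if it is invariant in
#' the stacked session series (`scope = "stacked"`).
#'
#' @param runs List of [bold_run()] objects of the same ROI.
#' @param scope "per_run" or "stacked".
#' @return List with `runs` (voxel-subset runs) and `kept` (indices).
#' @export
remove_invariant_voxels_runs <- function(runs,
                                         scope = c("per_run", "stacked")) {
  scope <- match.arg(scope)
  stopifnot(length(runs) >= 1L)
  nv <- nrow(runs[[1]]$data)
  if (scope == "per_run") {
    bad <- rep(FALSE, nv)
    for (r in runs) bad <- bad | apply(r$data, 1L, stats::var) == 0
  } else {
    stacked <- do.call(cbind, lapply(runs, `[[`, "data"))
    bad <- apply(stacked, 1L, stats::var) == 0
  }
  kept <- which(!bad)
  if (length(kept) == 0L)
    stop("remove_invariant_voxels_runs: all voxels invariant (empty ROI)")
  runs <- lapply(runs, function(r) {
    r$data <- r$data[kept, , drop = FALSE]
    r
  })
  list(runs = runs, kept = kept)
}

#' Run-wise normalization: linear detrend then z-score
#'
#' Within each run, each voxel's time series has its least-squares linear
#' trend removed and is then centered and scaled to unit standard
#' deviation. Discarded leading volumes are dropped first. Voxels with
#' zero residual variance after detrending (e.g. a pure linear trend) are
#' set to all zeros and reported via a warning and the `zeroed` attribute,
#' never silently scaled.
#'
#' @param runs List of [bold_run()] objects.
#' @return List of normalized runs; each carries an integer attribute
#'   `zeroed` with the indices of zeroed voxels.
#' @export
normalize_runs <- function(runs) {
  stopifnot(length(runs) >= 1L)
  lapply(runs, function(run) {
    run <- discard_volumes(run)
    x <- run$data
    nvol <- ncol(x)
    tt <- seq_len(nvol)
    tc <- tt - mean(tt)
    # closed-form least-squares detrend per voxel
    slope <- (x %*% tc) / sum(tc^2)
    resid <- x - mean_sweep(x) - slope %*% t(tc)
    s <- sqrt(rowSums(resid^2) / (nvol - 1L))
    zeroed <- which(s == 0)
    s[s == 0] <- 1
    out <- resid / s
    if (length(zeroed)) {
      out[zeroed, ] <- 0
      warning(sprintf(
        "normalize_runs: %d voxel(s) with zero residual variance zeroed in run '%s'",
        length(zeroed), run$run_id))
    }
    run$data <- out
    attr(run, "zeroed") <- zeroed
    run
  })
}

# subtract each row's mean
mean_sweep <- function(x) matrix(rowMeans(x), nrow(x), ncol(x))

#' Trial examples container
#'
#' @param features trial x voxel matrix (classification-window means).
#' @param labels Category per trial ("living"/"nonliving").
#' @param words,run_ids,conditions Labels per trial.
#' @param volume_stack Optional list of per-trial voxel x window matrices.
#' @param dropped Optional data.frame describing dropped trials.
#' @return Object of class `trial_examples`.
#' @export
trial_examples <- function(features, labels, words, run_ids,
                           conditions = NULL, volume_stack = NULL,
                           dropped = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(words),
            length(words) == length(run_ids))
  if (is.null(conditions)) conditions <- rep(NA_character_, length(labels))
  structure(list(features = features, labels = as.character(labels),
                 words = as.character(words),
                 run_ids = as.character(run_ids),
                 conditions = as.character(conditions),
                 volume_stack = volume_stack,
                 dropped = dropped),
            class = "trial_examples")
}

#' @export
print.trial_examples <- function(x, ...) {
  cat(sprintf("Trial examples: %d trials x %d voxels (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  if (!is.null(x$dropped) && nrow(x$dropped))
    cat(sprintf("  %d trial(s) dropped\n", nrow(x$dropped)))
  invisible(x)
}

#' Subset trial examples
#'
#' @param x A [trial_examples()] object.
#' @param i Logical or integer trial index.
#' @return The subset as a `trial_examples` object.
#' @export
subset_examples <- function(x, i) {
  trial_examples(x$features[i, , drop = FALSE], x$labels[i], x$words[i],
                 x$run_ids[i], x$conditions[i],
                 volume_stack = if (!is.null(x$volume_stack)) x$volume_stack[i],
                 dropped = x$dropped)
}

#' Extract per-trial examples from normalized runs
#'
#' For each non-catch trial the example window is the first six volumes
#' whose acquisition time is at or after onset + 3.4 s (capturing the
#' haemodynamic response between 3.4 and 8.6 s after word onset at
#' TR 0.85 s). The classifier feature vector is the mean over the subset
#' of those volumes acquired no later than onset + 6.8 s (five volumes at
#' TR 0.85), or over all six when `feature_window = "full"`. Trials whose
#' window runs past the end of the run are dropped and reported, not
#' raised as errors.
#'
#' @param runs List of normalized [bold_run()] objects of one ROI (see
#'   [normalize_runs()]).
#' @param events List of `event_table`s (or one table covering all runs)
#'   with onsets on the post-discard grid, seconds from the first retained
#'   volume.
#' @param feature_window "sub" (3.4-6.8 s mean, the default) or "full"
#'   (all six volumes).
#' @param onset_shift Seconds subtracted from every onset before window
#'   lookup; pass `n_discard * TR` when onsets are expressed on the full
#'   pre-discard clock (default 0: onsets already on the post-discard
#'   grid).
#' @param window_start,window_end,n_window_volumes Window parameters in
#'   seconds after onset (defaults 3.4, 6.8, 6).
#' @return A [trial_examples()] object; dropped trials are listed in its
#'   `dropped` element.
#' @export
extract_trial_examples <- function(runs, events, feature_window = c("sub", "full"),
                                   onset_shift = 0,
                                   window_start = 3.4, window_end = 6.8,
                                   n_window_volumes = 6L) {
  feature_window <- match.arg(feature_window)
  ev <- combine_events(events)
  feats <- list(); labs <- list(); wrds <- list(); rids <- list()
  conds <- list(); stacks <- list()
  dropped <- list()
  for (run in runs) {
    stopifnot(inherits(run, "bold_run"))
    if (run$n_discarded > 0L)
      stop("extract_trial_examples: runs must be normalized/discard-free")
    er <- ev[ev$run_id == run$run_id & !ev$is_catch, , drop = FALSE]
    if (!nrow(er)) next
    onsets <- er$onset - onset_shift
    times <- (seq_len(ncol(run$data)) - 1L) * run$tr
    for (t in seq_len(nrow(er))) {
      idx <- which(times >= onsets[t] + window_start)
      if (length(idx) < n_window_volumes) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(run_id = run$run_id, word = er$word[t],
                     onset = er$onset[t], reason = "window beyond run end",
                     stringsAsFactors = FALSE)
        next
      }
      idx <- idx[seq_len(n_window_volumes)]
      sub <- idx[times[idx] <= onsets[t] + window_end]
      use <- if (feature_window == "sub") sub else idx
      k <- length(feats) + 1L
      feats[[k]] <- rowMeans(run$data[, use, drop = FALSE])
      stacks[[k]] <- run$data[, idx, drop = FALSE]
      labs[[k]] <- er$category[t]
      wrds[[k]] <- er$word[t]
      rids[[k]] <- run$run_id
      conds[[k]] <- er$condition[t]
    }
  }
  if (!length(feats))
    stop("extract_trial_examples: no usable trials")
  trial_examples(do.call(rbind, feats), unlist(labs), unlist(wrds),
                 unlist(rids), unlist(conds), volume_stack = stacks,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else NULL)
}

combine_events <- function(events) {
  if (inherits(events, "data.frame")) return(events)
  do.call(rbind, lapply(events, as.data.frame))
}

#' Extract per-trial full volume sequences
#'
#' Partitions each run's retained volumes into per-trial blocks: a trial
#' owns the ordered volumes from its onset (first volume acquired at or
#' after it) up to the next trial's onset; the last trial extends to the
#' run end. Volumes before the first onset are unassigned. Each trial also
#' records which of its volumes fall in the 3.4-6.8 s post-onset training
#' window used by the discriminability analysis.
#'
#' @param runs List of normalized [bold_run()] objects of one ROI.
#' @param events List of `event_table`s (post-discard onsets).
#' @param include_catch Keep catch-trial blocks (default FALSE: they are
#'   dropped from the output after partitioning).
#' @param window_start,window_end Training window in seconds after onset.
#' @return Object of class `trial_volume_series`: `series` (list of
#'   voxel x volumes matrices), `info` (one row per trial: word, category,
#'   condition, run_id, onset, n_volumes), `train_cols` (list of column
#'   indices within each series falling in the training window).
#' @export
extract_trial_volume_series <- function(runs, events, include_catch = FALSE,
                                        window_start = 3.4,
                                        window_end = 6.8) {
  ev <- combine_events(events)
  series <- list(); train_cols <- list(); info <- list()
  for (run in runs) {
    if (run$n_discarded > 0L)
      stop("extract_trial_volume_series: runs must be normalized/discard-free")
    er <- ev[ev$run_id == run$run_id, , drop = FALSE]
    if (!nrow(er)) next
    nvol <- ncol(run$data)
    times <- (seq_len(nvol) - 1L) * run$tr
    starts <- vapply(er$onset, function(o) {
      i <- which(times >= o)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    if (anyNA(starts) || anyDuplicated(starts))
      stop("extract_trial_volume_series: trial windows overlap or fall outside run '",
           run$run_id, "'")
    ends <- c(starts[-1] - 1L, nvol)
    for (t in seq_len(nrow(er))) {
      if (!include_catch && er$is_catch[t]) next
      cols <- starts[t]:ends[t]
      k <- length(series) + 1L
      series[[k]] <- run$data[, cols, drop = FALSE]
      tw <- times[cols]
      train_cols[[k]] <- which(tw >= er$onset[t] + window_start &
                                 tw <= er$onset[t] + window_end)
      info[[k]] <- data.frame(
        word = er$word[t], category = er$category[t],
        condition = er$condition[t], run_id = run$run_id,
        onset = er$onset[t], n_volumes = length(cols),
        is_catch = er$is_catch[t], stringsAsFactors = FALSE)
    }
  }
  if (!length(series))
    stop("extract_trial_volume_series: no trials found")
  structure(list(series = series, info = do.call(rbind, info),
                 train_cols = train_cols),
            class = "trial_volume_series")
}

#' @export
print.trial_volume_series <- function(x, ...) {
  cat(sprintf("Trial volume series: %d trials, %d volumes total\n",
              length(x$series), sum(x$info$n_volumes)))
  invisible(x)
}
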