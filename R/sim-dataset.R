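#' Canonical double-gamma haemodynamic response function
#'
#' Standard two-gamma HRF (response peak 6 s, undershoot peak 16 s,
#' undershoot ratio 1/6), evaluated at arbitrary times; zero for t < 0.
#'
#' @param t Numeric vector of times in seconds.
#' @param peak,undershoot Gamma shape parameters (scale 1 s).
#' @param ratio Undershoot amplitude relative to the peak.
#' @return Numeric vector, the HRF normalized to unit maximum.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- ifelse(t < 0, 0,
              stats::dgamma(t, shape = peak, rate = 1) -
                ratio * stats::dgamma(t, shape = undershoot, rate = 1))
  # unit peak so planted gains are interpretable as response amplitudes
  grid <- seq(0, 32, by = 0.01)
  mx <- max(stats::dgamma(grid, shape = peak, rate = 1) -
              ratio * stats::dgamma(grid, shape = undershoot, rate = 1))
  h / mx
}

#' BOLD run container
#'
#' @param data voxel x volume numeric matrix.
#' @param tr Repetition time in seconds.
#' @param run_id,roi_id Labels.
#' @param n_discarded Leading volumes to discard before analysis.
#' @return Object of class `bold_run`.
#' @export
bold_run <- function(data, tr, run_id, roi_id, n_discarded = 0L) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("bold_run: non-finite entries in 'data'")
  if (ncol(data) <= n_discarded)
    stop("bold_run: volume count must exceed 'n_discarded'")
  structure(list(data = data, tr = tr, run_id = run_id, roi_id = roi_id,
                 n_discarded = as.integer(n_discarded)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("BOLD run %s / ROI %s: %d voxels x %d volumes (TR %.3g s, %d discarded)\n",
              x$run_id, x$roi_id, nrow(x$data), ncol(x$data), x$tr,
              x$n_discarded))
  invisible(x)
}

# latent-normal correlation giving Pearson correlation s between the
# pnorm-transformed (uniform) gating series of a Gaussian copula
copula_rho <- function(s) 2 * sin(pi * s / 6)

# centred unit-norm pattern vector over voxels (zero ROI mean so gating
# fluctuations do not leak into the ROI-mean time course)
centred_pattern <- function(n) {
  v <- stats::rnorm(n)
  v <- v - mean(v)
  v / sqrt(sum(v^2) / n)
}

#' Generate a full synthetic multi-ROI dataset
#'
#' Simulates per-ROI, per-run BOLD matrices under the event-related design:
#' baseline + linear drift + low-frequency cosine drift + white Gaussian
#' noise + the HRF-convolved trial signal. The signal of trial t (word w,
#' category c) is `gating[t] * (gain_cond * category_pattern[, c] +
#' word_gain * word_pattern[, w])`, where `gain_cond` is the ROI's deep or
#' shallow category gain depending on the run's condition, and `gating` is
#' a per-trial multiplier in [0, 1]. Gating series of coupled ROI pairs are
#' drawn from a Gaussian copula so their Pearson correlation matches the
#' configured coupling strength (optionally within one condition only);
#' uncoupled ROIs' series are independent. Catch trials carry no planted
#' signal.
#'
#' @param config A [sim_config()].
#' @return List with elements
#'   \describe{
#'     \item{bold}{named list over ROIs; each a list over runs of
#'       [bold_run()] objects.}
#'     \item{events}{list of per-run `event_table`s (onsets on the
#'       post-discard grid).}
#'     \item{masks}{named integer vector of voxels per ROI.}
#'     \item{ground_truth}{class `ground_truth`: planted category and word
#'       patterns, gating series, coupling pairs.}
#'   }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rois <- config$roi_specs
  roi_names <- names(rois)

  # one ROI may take part in at most one coupling pair
  cp_rois <- unlist(lapply(config$coupling, function(cp) c(cp$roi_a, cp$roi_b)))
  if (anyDuplicated(cp_rois))
    stop("generate_dataset: an ROI may appear in at most one coupling pair")

  events <- lapply(seq_len(config$n_runs) - 1L,
                   function(i) generate_schedule(config, i))

  words <- c(config$word_pool$living, config$word_pool$nonliving)
  word_cat <- rep(c("living", "nonliving"), each = config$n_words_per_category)
  names(word_cat) <- words

  category_patterns <- lapply(rois, function(rs) {
    m <- cbind(living = centred_pattern(rs$n_voxels),
               nonliving = centred_pattern(rs$n_voxels))
    m
  })
  word_patterns <- lapply(rois, function(rs) {
    m <- vapply(words, function(w) centred_pattern(rs$n_voxels),
                numeric(rs$n_voxels))
    colnames(m) <- words
    m
  })

  # per-ROI latent gating normals, one per event row per run
  n_ev <- vapply(events, nrow, integer(1))
  total_ev <- sum(n_ev)
  run_of_ev <- rep(seq_len(config$n_runs), n_ev)
  cond_of_ev <- config$condition_order[run_of_ev]
  latent <- lapply(roi_names, function(r) stats::rnorm(total_ev))
  names(latent) <- roi_names
  for (cp in config$coupling) {
    sel <- if (cp$condition == "both") rep(TRUE, total_ev)
           else cond_of_ev == cp$condition
    rho <- copula_rho(cp$strength)
    e <- stats::rnorm(sum(sel))
    latent[[cp$roi_b]][sel] <-
      rho * latent[[cp$roi_a]][sel] + sqrt(1 - rho^2) * e
  }
  gating <- lapply(latent, stats::pnorm)

  v_times <- (seq_len(config$volumes_per_run) - 1L) * config$tr
  run_dur <- config$volumes_per_run * config$tr
  shift <- config$n_discard * config$tr

  bold <- lapply(roi_names, function(r) {
    rs <- rois[[r]]
    lapply(seq_len(config$n_runs), function(i) {
      ev <- events[[i]]
      gain_cond <- if (config$condition_order[i] == "deep")
        rs$category_gain_deep else rs$category_gain_shallow
      g <- gating[[r]][run_of_ev == i]
      amp <- matrix(0, rs$n_voxels, nrow(ev))
      for (t in seq_len(nrow(ev))) {
        if (ev$is_catch[t]) next
        w <- ev$word[t]
        amp[, t] <- g[t] *
          (gain_cond * category_patterns[[r]][, word_cat[[w]]] +
             rs$word_gain * word_patterns[[r]][, w])
      }
      # HRF regressor per trial, events on the full (pre-discard) clock
      H <- vapply(seq_len(nrow(ev)),
                  function(t) hrf_double_gamma(v_times - (ev$onset[t] + shift)),
                  numeric(config$volumes_per_run))
      slope <- stats::rnorm(rs$n_voxels)
      cosamp <- stats::rnorm(rs$n_voxels)
      drift <- rs$drift_amplitude *
        (outer(slope, v_times / run_dur - 0.5) +
           outer(cosamp, cos(2 * pi * v_times / run_dur)))
      noise <- matrix(stats::rnorm(rs$n_voxels * config$volumes_per_run,
                                   sd = rs$noise_sd),
                      rs$n_voxels, config$volumes_per_run)
      dat <- config$baseline + drift + noise + amp %*% t(H)
      bold_run(dat, tr = config$tr, run_id = ev$run_id[1], roi_id = r,
               n_discarded = config$n_discard)
    })
  })
  names(bold) <- roi_names

  gating_df <- data.frame(
    run_id = sprintf("run%02d", run_of_ev),
    condition = cond_of_ev,
    stringsAsFactors = FALSE
  )
  for (r in roi_names) gating_df[[r]] <- gating[[r]]

  gt <- structure(
    list(category_patterns = category_patterns,
         word_patterns = word_patterns,
         gating_series = gating_df,
         coupling_pairs = config$coupling,
         feature_map = NULL),
    class = "ground_truth"
  )
  masks <- vapply(rois, `[[`, integer(1), "n_voxels")
  list(bold = bold, events = events, masks = masks, ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d ROI(s), %d word patterns, %d coupling pair(s)\n",
              length(x$category_patterns),
              ncol(x$word_patterns[[1]]), length(x$coupling_pairs)))
  invisible(x)
}
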