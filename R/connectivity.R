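#' Leave-one-trial-out discriminability time series
#'
#' For each trial in turn, a PCA + linear-SVM classifier is trained on the
#' individual volumes inside every other trial's 3.4-6.8 s post-onset
#' window (each volume a training sample labelled with its trial's
#' category) and tested on all volumes of the left-out trial, not confined
#' to any sub-interval. For every tested volume, the estimated probability
#' of the trial's true category is recorded; concatenating over trials in
#' volume order yields a per-volume discriminability trace for the ROI.
#'
#' @param tvs A `trial_volume_series` from
#'   [extract_trial_volume_series()] (one ROI, one condition's runs).
#' @param spec A [classifier_spec()]; its `probability_mode` selects
#'   Platt-calibrated or sigmoid-of-decision probabilities.
#' @param roi,condition Labels stored in the result.
#' @return Object of class `discrim_ts`: `values` (probability correct per
#'   volume, in [0, 1]), `trial_index` (trial each volume belongs to),
#'   `skipped` (indices of trials without a usable training window).
#' @export
discriminability_timeseries <- function(tvs, spec = classifier_spec(),
                                        roi = NA_character_,
                                        condition = NA_character_) {
  stopifnot(inherits(tvs, "trial_volume_series"))
  n_trials <- length(tvs$series)
  usable <- which(vapply(tvs$train_cols, length, integer(1)) > 0L)
  skipped <- setdiff(seq_len(n_trials), usable)
  if (length(skipped))
    warning(sprintf(
      "discriminability_timeseries: %d trial(s) without training window skipped",
      length(skipped)))
  cats <- tvs$info$category
  if (length(unique(cats[usable])) < 2L ||
      min(table(cats[usable])) < 2L)
    stop("discriminability_timeseries: need >= 2 trials per class")

  train_x <- lapply(usable, function(t)
    t(tvs$series[[t]][, tvs$train_cols[[t]], drop = FALSE]))
  train_n <- vapply(train_x, nrow, integer(1))

  values <- list(); trial_index <- list()
  for (k in seq_along(usable)) {
    t <- usable[k]
    x_tr <- do.call(rbind, train_x[-k])
    y_tr <- rep(cats[usable][-k], train_n[-k])
    model <- fit_pca_svm(x_tr, y_tr, spec)
    probs <- model$predict_prob(t(tvs$series[[t]]))
    values[[k]] <- probs[, cats[t]]
    trial_index[[k]] <- rep(t, nrow(probs))
  }
  structure(list(roi = roi, condition = condition,
                 values = unlist(values, use.names = FALSE),
                 trial_index = unlist(trial_index),
                 skipped = skipped),
            class = "discrim_ts")
}

#' @export
print.discrim_ts <- function(x, ...) {
  cat(sprintf("Discriminability series%s: %d volumes, mean p(correct) %.3f\n",
              if (!is.na(x$roi)) sprintf(" %s/%s", x$roi, x$condition) else "",
              length(x$values), mean(x$values)))
  invisible(x)
}

connectivity_matrix <- function(r, rois, kind, condition = NA_character_) {
  dimnames(r) <- list(rois, rois)
  diag(r) <- NA_real_
  structure(list(rois = rois, r = r, kind = kind, condition = condition),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("%s connectivity (%s): %d ROIs\n",
              x$kind,
              ifelse(is.na(x$condition), "all", x$condition),
              length(x$rois)))
  print(round(x$r, 3))
  invisible(x)
}

#' Informational connectivity matrix
#'
#' Pairwise Pearson correlation between per-ROI discriminability time
#' series. A constant series yields undefined correlations, recorded as
#' NA with a warning (never as zero).
#'
#' @param ts_list List of [discriminability_timeseries()] results (or
#'   plain numeric vectors), one per ROI, all of the same length and
#'   volume alignment; names give ROI labels.
#' @param condition Optional condition label.
#' @return A `connectivity_matrix` of kind "informational".
#' @export
informational_connectivity <- function(ts_list, condition = NA_character_) {
  vals <- lapply(ts_list, function(x)
    if (inherits(x, "discrim_ts")) x$values else as.numeric(x))
  lens <- vapply(vals, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("informational_connectivity: series lengths differ")
  rois <- names(ts_list)
  if (is.null(rois))
    rois <- vapply(seq_along(ts_list), function(i) {
      r <- if (inherits(ts_list[[i]], "discrim_ts")) ts_list[[i]]$roi
           else NA_character_
      if (is.na(r)) sprintf("roi%d", i) else r
    }, character(1))
  m <- do.call(cbind, vals)
  if (any(apply(m, 2L, stats::sd) == 0)) {
    warning("informational_connectivity: constant series; correlations set to NA")
    r <- suppressWarnings(stats::cor(m))
  } else {
    r <- stats::cor(m)
  }
  connectivity_matrix(r, rois, "informational", condition)
}

#' Functional connectivity matrix
#'
#' The ROI-mean BOLD time course (mean over voxels per volume,
#' concatenated over the supplied runs) is correlated between every pair
#' of ROIs.
#'
#' @param runs_by_roi Named list: ROI -> list of normalized [bold_run()]
#'   objects sharing the scan grid.
#' @param condition Optional condition label.
#' @return A `connectivity_matrix` of kind "functional".
#' @export
functional_connectivity <- function(runs_by_roi,
                                    condition = NA_character_) {
  rois <- names(runs_by_roi)
  stopifnot(!is.null(rois))
  series <- lapply(runs_by_roi, function(runs) {
    unlist(lapply(runs, function(r) {
      if (nrow(r$data) == 0L) stop("functional_connectivity: empty ROI")
      colMeans(r$data)
    }), use.names = FALSE)
  })
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("functional_connectivity: ROIs do not share the scan grid")
  r <- stats::cor(do.call(cbind, series))
  connectivity_matrix(r, rois, "functional", condition)
}

#' Permutation effect size for informational connectivity
#'
#' The observed Pearson correlation between two discriminability series
#' is compared with a null distribution obtained by shuffling the first
#' series `n_perm` times and re-correlating with the intact second
#' series. The effect size is
#' `(r_true - mean(null)) / var(null)` - the division by the variance
#' (not the standard deviation) follows the stated formula; set
#' `use_sd = TRUE` for the sd-scaled variant. The measure does not depend
#' on the absolute level of classification performance.
#'
#' @param ts_a,ts_b Discriminability series ([discriminability_timeseries()]
#'   results or numeric vectors) of equal length >= 3.
#' @param n_perm Number of shuffles (default 10000; fewer than 100 draws
#'   a warning).
#' @param seed Optional integer seed.
#' @param use_sd Scale by the null standard deviation instead of the
#'   variance.
#' @return Object of class `perm_effect`: r_true, null_mean, null_var,
#'   effect, n_perm.
#' @export
permutation_effect_size <- function(ts_a, ts_b, n_perm = 10000,
                                    seed = NULL, use_sd = FALSE) {
  a <- if (inherits(ts_a, "discrim_ts")) ts_a$values else as.numeric(ts_a)
  b <- if (inherits(ts_b, "discrim_ts")) ts_b$values else as.numeric(ts_b)
  if (length(a) != length(b) || length(a) < 3L)
    stop("permutation_effect_size: series must have equal length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("permutation_effect_size: constant input series")
  if (n_perm < 100L)
    warning("permutation_effect_size: fewer than 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  r_true <- stats::cor(a, b)
  null_r <- vapply(seq_len(n_perm),
                   function(i) stats::cor(sample(a), b), numeric(1))
  null_mean <- mean(null_r)
  null_var <- stats::var(null_r)
  denom <- if (use_sd) sqrt(null_var) else null_var
  structure(list(r_true = r_true, null_mean = null_mean,
                 null_var = null_var, effect = (r_true - null_mean) / denom,
                 n_perm = as.integer(n_perm), use_sd = use_sd),
            class = "perm_effect")
}

#' @export
print.perm_effect <- function(x, ...) {
  cat(sprintf(
    "Permutation effect size: r = %.4f, null mean %.4f, null var %.2e, effect %.2f (%d perms)\n",
    x$r_true, x$null_mean, x$null_var, x$effect, x$n_perm))
  invisible(x)
}

#' Paired condition contrast of connectivity matrices
#'
#' For every ROI pair, a paired t-test on the per-subject deep - shallow
#' matrix entries, FDR-corrected across pairs. Signs are retained so
#' pairs stronger in the shallow condition are reportable. Pairs with
#' missing entries in any subject are excluded and reported.
#'
#' @param matrices_deep,matrices_shallow Lists (one element per subject)
#'   of `connectivity_matrix` objects or plain symmetric matrices with
#'   identical ROI ordering.
#' @param q Rejection threshold on the FDR-adjusted p-value.
#' @return A `stat_table` data.frame with one row per tested ROI pair
#'   (roi_a, roi_b, statistic, df, p, q, reject, effect_direction);
#'   excluded pairs are listed in the `excluded` attribute.
#' @export
condition_contrast <- function(matrices_deep, matrices_shallow, q = 0.05) {
  getm <- function(x) if (inherits(x, "connectivity_matrix")) x$r else as.matrix(x)
  md <- lapply(matrices_deep, getm)
  ms <- lapply(matrices_shallow, getm)
  n_subj <- length(md)
  if (n_subj < 3L) stop("condition_contrast: need >= 3 subjects")
  if (length(ms) != n_subj)
    stop("condition_contrast: unmatched subject lists")
  rois <- rownames(md[[1]])
  if (is.null(rois)) rois <- sprintf("roi%d", seq_len(nrow(md[[1]])))
  n <- length(rois)
  pairs <- which(upper.tri(md[[1]]), arr.ind = TRUE)
  rows <- list(); excluded <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dv <- vapply(md, function(m) m[i, j], numeric(1))
    sv <- vapply(ms, function(m) m[i, j], numeric(1))
    if (anyNA(dv) || anyNA(sv)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(roi_a = rois[i], roi_b = rois[j],
                   reason = "missing entries", stringsAsFactors = FALSE)
      next
    }
    tt <- paired_t(dv, sv)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_a = rois[i], roi_b = rois[j], statistic = tt$statistic,
      df = tt$df, p = tt$p, effect_direction = sign(mean(dv - sv)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("condition_contrast: no testable pairs")
  out <- do.call(rbind, rows)
  f <- fdr_bh(out$p, q = q)
  out$q <- f$q; out$reject <- f$reject
  rownames(out) <- NULL
  class(out) <- c("stat_table", "data.frame")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else NULL
  out
}
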