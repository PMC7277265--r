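#' Linear classifier specification
#'
#' Fixes the decoding classifier: a linear max-margin (support-vector)
#' decision rule with l2 regularization, cost C and numerical tolerance,
#' and the way class probabilities are derived from it (Platt-style
#' logistic calibration of training decision values, or a plain sigmoid
#' of the decision value).
#'
#' @param cost Soft-margin cost C (default 1.0).
#' @param tolerance Optimizer tolerance (default 1e-4).
#' @param probability_mode "platt" or "sigmoid_decision".
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(cost = 1.0, tolerance = 1e-4,
                            probability_mode = c("platt", "sigmoid_decision")) {
  if (!is.finite(cost) || cost <= 0) stop("classifier_spec: 'cost' must be > 0")
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("classifier_spec: 'tolerance' must be > 0")
  structure(list(penalty = "l2", cost = cost, tolerance = tolerance,
                 probability_mode = match.arg(probability_mode)),
            class = "classifier_spec")
}

#' Balanced stratified shuffle splits
#'
#' Repeated random train-test partitions with exact class balance on both
#' sides: the per-class test count is `round(n_class * test_fraction)`
#' with ties (.5) broken toward the smaller test set, the remainder
#' trains.
#'
#' @param labels Class label per trial (two classes).
#' @param n_splits Number of splits (default 300).
#' @param test_fraction Test proportion (default 0.2).
#' @param seed Optional integer seed.
#' @return List of `cv_split` objects (fields `train`, `test`, `scheme`,
#'   `meta`).
#' @export
make_stratified_splits <- function(labels, n_splits = 300,
                                   test_fraction = 0.2, seed = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop("make_stratified_splits: class '",
         names(counts)[which.min(counts)], "' has fewer than 2 examples")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("make_stratified_splits: 'test_fraction' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  idx_by_class <- split(seq_along(labels), labels)
  n_test <- vapply(idx_by_class, function(ix) {
    x <- length(ix) * test_fraction
    # ties toward the smaller test set
    as.integer(ceiling(x - 0.5))
  }, integer(1))
  if (any(n_test < 1) || any(n_test >= counts))
    stop("make_stratified_splits: test fraction leaves a class empty on one side")
  lapply(seq_len(n_splits), function(s) {
    test <- unlist(lapply(classes, function(cl) {
      sample(idx_by_class[[cl]], n_test[[cl]])
    }), use.names = FALSE)
    cv_split(setdiff(seq_along(labels), test), test,
             scheme = "stratified_shuffle", meta = s)
  })
}

cv_split <- function(train, test, scheme, meta = NULL) {
  if (length(intersect(train, test)))
    stop("cv_split: train and test overlap")
  structure(list(train = as.integer(train), test = as.integer(test),
                 scheme = scheme, meta = meta),
            class = "cv_split")
}

#' Out-of-sample word-pair splits
#'
#' One split per (living word, non-living word) pair: all trials of the
#' two held-out words form the test set and never appear in training, so
#' accuracy measures category-level generalization to unseen words.
#'
#' @param words Word label per trial.
#' @param labels Category per trial (two classes).
#' @param n_pairs Optional number of pairs to subsample (default: all).
#' @param seed Seed for the subsample.
#' @return List of `cv_split` objects; `meta` holds the held-out pair.
#' @export
make_word_pair_splits <- function(words, labels, n_pairs = NULL,
                                  seed = NULL) {
  words <- as.character(words); labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("make_word_pair_splits: words must map to exactly two classes")
  wl <- unique(words[labels == classes[1]])
  wn <- unique(words[labels == classes[2]])
  zero <- vapply(c(wl, wn), function(w) sum(words == w) == 0, logical(1))
  if (any(zero)) stop("make_word_pair_splits: word with zero trials")
  pairs <- expand.grid(a = wl, b = wn, stringsAsFactors = FALSE)
  if (!is.null(n_pairs) && n_pairs < nrow(pairs)) {
    if (!is.null(seed)) set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
  }
  lapply(seq_len(nrow(pairs)), function(i) {
    held <- c(pairs$a[i], pairs$b[i])
    test <- which(words %in% held)
    train <- which(!words %in% held)
    if (!length(train))
      stop("make_word_pair_splits: empty training set (too few words)")
    cv_split(train, test, scheme = "word_pair", meta = held)
  })
}

#' Leave-one-run-out splits
#'
#' @param run_ids Run label per trial (>= 2 distinct runs).
#' @return List of `cv_split` objects, one per run; `meta` holds the
#'   held-out run. Few-fold estimates are unstable, so a warning notes
#'   the fold count when it is below 6.
#' @export
make_run_splits <- function(run_ids) {
  run_ids <- as.character(run_ids)
  runs <- unique(run_ids)
  if (length(runs) < 2L)
    stop("make_run_splits: need at least 2 runs")
  if (length(runs) < 6L)
    warning(sprintf(
      "make_run_splits: only %d cross-validation folds; leave-one-run-out estimates can be unstable",
      length(runs)))
  lapply(runs, function(r) {
    cv_split(which(run_ids != r), which(run_ids == r),
             scheme = "run", meta = r)
  })
}

# PCA + linear SVM fit on training rows; returns a predictor closure.
# Component count = min(n_train, n_features): an information-lossless
# rotation into the subspace spanned by the training examples.
fit_pca_svm <- function(x_train, y_train, spec) {
  if (any(!is.finite(x_train))) stop("decode: non-finite features")
  if (nrow(x_train) < 2L) stop("decode: PCA needs at least 2 training examples")
  y_train <- factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L)
    stop("decode: training set contains a single class")
  rank <- min(nrow(x_train), ncol(x_train))
  pca <- stats::prcomp(x_train, center = TRUE, scale. = FALSE, rank. = rank)
  z_train <- pca$x
  fit <- e1071::svm(z_train, y_train, kernel = "linear",
                    cost = spec$cost, tolerance = spec$tolerance,
                    scale = FALSE)
  platt <- NULL
  if (spec$probability_mode == "platt") {
    dv_obj <- attr(stats::predict(fit, z_train, decision.values = TRUE),
                   "decision.values")
    # e1071 names the decision column "A/B": positive values favour A
    first_lab <- sub("/.*", "", colnames(dv_obj))
    y_first <- as.integer(as.character(y_train) == first_lab)
    platt <- suppressWarnings(
      stats::glm(y_first ~ dv, family = stats::binomial(),
                 data = data.frame(dv = dv_obj[, 1])))
  }
  list(
    predict_class = function(x_new) {
      z <- scale(x_new, center = pca$center, scale = FALSE) %*% pca$rotation
      as.character(stats::predict(fit, z))
    },
    predict_prob = function(x_new) {
      # probability of each class, columns named by class
      z <- scale(x_new, center = pca$center, scale = FALSE) %*% pca$rotation
      dv <- attr(stats::predict(fit, z, decision.values = TRUE),
                 "decision.values")
      first <- sub("/.*", "", colnames(dv))
      second <- sub(".*/", "", colnames(dv))
      p_first <- if (!is.null(platt)) {
        as.numeric(stats::predict(platt, newdata = data.frame(dv = dv[, 1]),
                                  type = "response"))
      } else {
        1 / (1 + exp(-dv[, 1]))
      }
      out <- cbind(p_first, 1 - p_first)
      colnames(out) <- c(first, second)
      out
    }
  )
}

#' Decode category from trial examples under a set of splits
#'
#' For every split, principal components are estimated on the training
#' examples (component count = number of training examples, capped at the
#' voxel count: an information-lossless rotation), train and test data
#' are projected, a linear max-margin classifier is fitted on the
#' projected training data, and test accuracy is recorded. Accuracies are
#' aggregated over splits.
#'
#' @param examples A [trial_examples()] object.
#' @param splits List of splits from [make_stratified_splits()],
#'   [make_word_pair_splits()] or [make_run_splits()].
#' @param spec A [classifier_spec()].
#' @param use_pca Set FALSE to fit the classifier on raw voxel features
#'   (for checking that the rotation loses no information).
#' @param roi,condition Optional labels stored in the result.
#' @return Object of class `decoding_result` with `per_split_accuracy`
#'   and `mean_accuracy`.
#' @export
decode <- function(examples, splits, spec = classifier_spec(),
                   use_pca = TRUE, roi = NA_character_,
                   condition = NA_character_) {
  stopifnot(inherits(examples, "trial_examples"))
  if (any(!is.finite(examples$features)))
    stop("decode: non-finite features")
  acc <- vapply(splits, function(sp) {
    x_tr <- examples$features[sp$train, , drop = FALSE]
    y_tr <- examples$labels[sp$train]
    x_te <- examples$features[sp$test, , drop = FALSE]
    y_te <- examples$labels[sp$test]
    if (use_pca) {
      model <- fit_pca_svm(x_tr, y_tr, spec)
      pred <- model$predict_class(x_te)
    } else {
      fit <- e1071::svm(x_tr, factor(y_tr), kernel = "linear",
                        cost = spec$cost, tolerance = spec$tolerance,
                        scale = FALSE)
      pred <- as.character(stats::predict(fit, x_te))
    }
    mean(pred == y_te)
  }, numeric(1))
  structure(list(roi = roi, condition = condition,
                 scheme = splits[[1]]$scheme,
                 per_split_accuracy = acc, mean_accuracy = mean(acc),
                 classifier = spec, n_splits = length(splits)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result [%s]%s: mean accuracy %.4f over %d splits\n",
              x$scheme,
              if (!is.na(x$roi)) sprintf(" %s/%s", x$roi, x$condition) else "",
              x$mean_accuracy, x$n_splits))
  invisible(x)
}

#' @export
summary.decoding_result <- function(object, ...) {
  acc <- object$per_split_accuracy
  cat(sprintf("Decoding [%s]: mean %.4f, sd %.4f, range [%.3f, %.3f], %d splits\n",
              object$scheme, mean(acc), stats::sd(acc), min(acc), max(acc),
              length(acc)))
  invisible(object)
}

#' Group-level decoding statistics
#'
#' One-sample t-tests of per-subject mean accuracy against chance (0.5)
#' for every ROI within each condition, and paired t-tests of
#' deep - shallow accuracy per ROI; each family is FDR-corrected
#' (Benjamini-Hochberg) separately.
#'
#' @param results data.frame with columns subject, roi, condition,
#'   accuracy (one row per subject x ROI x condition).
#' @param chance Chance accuracy (default 0.5).
#' @param q Rejection threshold on the FDR-adjusted p-value.
#' @return List of two `stat_table` data.frames: `vs_chance` and
#'   `deep_vs_shallow`.
#' @export
group_level_stats <- function(results, chance = 0.5, q = 0.05) {
  needed <- c("subject", "roi", "condition", "accuracy")
  stopifnot(all(needed %in% names(results)))
  n_subj <- length(unique(results$subject))
  if (n_subj < 3L) stop("group_level_stats: need at least 3 subjects")

  vs_chance <- do.call(rbind, lapply(split(
    results, results[c("roi", "condition")], drop = TRUE), function(d) {
      tt <- one_sample_t(d$accuracy, mu = chance)
      data.frame(roi = d$roi[1], condition = d$condition[1],
                 statistic = tt$statistic, df = tt$df, p = tt$p,
                 effect_direction = sign(mean(d$accuracy) - chance),
                 stringsAsFactors = FALSE)
    }))
  vs_chance <- do.call(rbind, lapply(
    split(vs_chance, vs_chance$condition), function(d) {
      f <- fdr_bh(d$p, q = q)
      d$q <- f$q; d$reject <- f$reject
      d
    }))

  wide <- stats::reshape(
    results[order(results$subject), needed], direction = "wide",
    idvar = c("subject", "roi"), timevar = "condition")
  if (anyNA(wide))
    stop("group_level_stats: subject sets differ between conditions")
  pairs <- do.call(rbind, lapply(split(wide, wide$roi), function(d) {
    tt <- paired_t(d$accuracy.deep, d$accuracy.shallow)
    data.frame(roi = d$roi[1], statistic = tt$statistic, df = tt$df,
               p = tt$p,
               effect_direction = sign(mean(d$accuracy.deep -
                                              d$accuracy.shallow)),
               stringsAsFactors = FALSE)
  }))
  f <- fdr_bh(pairs$p, q = q)
  pairs$q <- f$q; pairs$reject <- f$reject
  rownames(vs_chance) <- rownames(pairs) <- NULL
  list(vs_chance = vs_chance, deep_vs_shallow = pairs)
}
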