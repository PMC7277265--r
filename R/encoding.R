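#' Encoding model specification
#'
#' @param alpha Ridge penalty (default 100).
#' @param n_folds Number of stratified shuffle folds (default 300).
#' @param test_fraction Held-out proportion per fold (default 0.2).
#' @param seed Integer seed for the fold generator.
#' @return Object of class `encoding_spec`.
#' @export
encoding_spec <- function(alpha = 100, n_folds = 300, test_fraction = 0.2,
                          seed = 1L) {
  if (!is.finite(alpha) || alpha <= 0)
    stop("encoding_spec: 'alpha' must be > 0")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("encoding_spec: 'test_fraction' must be in (0, 1)")
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "encoding_spec")
}

# closed-form ridge: standardized X (train moments), mean-centred Y,
# W = (X'X + alpha I)^-1 X'Y; prediction adds the training target mean
ridge_fit <- function(x_train, y_train, alpha) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x_train, 2L, mu), 2L, sdv, "/")
  ym <- colMeans(y_train)
  yc <- sweep(y_train, 2L, ym)
  p <- ncol(xs)
  w <- solve(crossprod(xs) + alpha * diag(p), crossprod(xs, yc))
  list(predict = function(x_new) {
    xn <- sweep(sweep(x_new, 2L, mu), 2L, sdv, "/")
    sweep(xn %*% w, 2L, ym, "+")
  }, weights = w, x_center = mu, x_scale = sdv, y_mean = ym)
}

# per-column R^2 of predictions vs observed, around the test-sample mean
r2_score <- function(y, yhat) {
  ss_res <- colSums((y - yhat)^2)
  ybar <- colMeans(y)
  ss_tot <- colSums(sweep(y, 2L, ybar)^2)
  out <- 1 - ss_res / ss_tot
  out[ss_tot == 0] <- 0
  out
}

# expand word-level features to one row per trial
expand_features <- function(features, words) {
  stopifnot(inherits(features, "feature_matrix"))
  miss <- setdiff(unique(words), features$words)
  if (length(miss))
    stop("expand_features: no feature row for word(s): ",
         paste(miss, collapse = ", "))
  features$matrix[words, , drop = FALSE]
}

#' Fit a voxelwise ridge encoding model
#'
#' Maps stimulus feature vectors to voxel responses with l2-regularized
#' (ridge) regression under repeated stratified train-test folds.
#' Per fold, features are standardized using training-row moments, the
#' ridge solution is fitted on the training rows, and the proportion of
#' variance explained (R-squared; at most 1, negative when worse than
#' predicting the mean) is computed per voxel on the held-out rows.
#' Category labels are used only to stratify the folds, never in
#' fitting. Per-voxel scores are averaged over folds; voxels with
#' positive average variance explained form the `positive_voxels` set,
#' and the aggregate score is their mean (the mean over all voxels is
#' also reported).
#'
#' @param features A [feature_matrix()] (word-level rows; expanded to
#'   trials via the example words) or a trial x dimension matrix already
#'   aligned to trials.
#' @param examples A [trial_examples()] object (targets = its feature
#'   matrix, trials x voxels).
#' @param spec An [encoding_spec()].
#' @param shuffle_features Internal: row-shuffle the training-fold
#'   features before fitting (the empirical-chance pipeline).
#' @param roi,condition,model_name Optional labels stored in the result.
#' @return Object of class `encoding_result` with per-voxel average
#'   variance explained (`voxel_ve`), `positive_voxels`,
#'   `aggregate_ve` (mean over positive voxels), `aggregate_ve_all`
#'   (mean over all voxels), and fold bookkeeping.
#' @export
fit_encoding <- function(features, examples, spec = encoding_spec(),
                         shuffle_features = FALSE, roi = NA_character_,
                         condition = NA_character_,
                         model_name = NULL) {
  stopifnot(inherits(examples, "trial_examples"))
  x <- if (inherits(features, "feature_matrix")) {
    if (is.null(model_name)) model_name <- features$model_name
    expand_features(features, examples$words)
  } else as.matrix(features)
  y <- examples$features
  if (nrow(x) != nrow(y))
    stop("fit_encoding: feature rows not aligned to trials")
  if (nrow(x) < 10L) stop("fit_encoding: need at least 10 trials")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("fit_encoding: non-finite inputs")

  splits <- make_stratified_splits(examples$labels, n_splits = spec$n_folds,
                                   test_fraction = spec$test_fraction,
                                   seed = spec$seed)
  ve_sum <- numeric(ncol(y))
  for (sp in splits) {
    x_tr <- x[sp$train, , drop = FALSE]
    if (shuffle_features)
      x_tr <- x_tr[sample.int(nrow(x_tr)), , drop = FALSE]
    fit <- ridge_fit(x_tr, y[sp$train, , drop = FALSE], spec$alpha)
    yhat <- fit$predict(x[sp$test, , drop = FALSE])
    ve_sum <- ve_sum + r2_score(y[sp$test, , drop = FALSE], yhat)
  }
  voxel_ve <- ve_sum / length(splits)
  pos <- which(voxel_ve > 0)
  structure(list(
    roi = roi, condition = condition, model_name = model_name,
    voxel_ve = voxel_ve, positive_voxels = pos,
    aggregate_ve = if (length(pos)) mean(voxel_ve[pos]) else NA_real_,
    aggregate_ve_all = mean(voxel_ve),
    n_folds = length(splits), alpha = spec$alpha,
    shuffled = shuffle_features),
    class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf(
    "Encoding result%s%s: %d voxels, %d positive; mean VE %.4f (positive), %.4f (all)%s\n",
    if (!is.null(x$model_name)) sprintf(" [%s]", x$model_name) else "",
    if (!is.na(x$roi)) sprintf(" %s/%s", x$roi, x$condition) else "",
    length(x$voxel_ve), length(x$positive_voxels),
    x$aggregate_ve, x$aggregate_ve_all,
    if (x$shuffled) " (shuffled-features chance run)" else ""))
  invisible(x)
}

#' @export
summary.encoding_result <- function(object, ...) {
  v <- object$voxel_ve
  cat(sprintf(
    "Encoding VE over %d voxels: min %.4f, median %.4f, max %.4f; %d positive (%.0f%%)\n",
    length(v), min(v), stats::median(v), max(v),
    length(object$positive_voxels),
    100 * length(object$positive_voxels) / length(v)))
  invisible(object)
}

#' Empirical chance level of an encoding model
#'
#' Runs the identical cross-validated ridge pipeline except that the
#' training-fold feature rows are shuffled against the intact targets
#' before each fit, destroying the feature-target mapping while keeping
#' both marginals.
#'
#' @inheritParams fit_encoding
#' @return An `encoding_result` whose scores estimate the chance level.
#' @export
empirical_chance <- function(features, examples, spec = encoding_spec(),
                             roi = NA_character_,
                             condition = NA_character_,
                             model_name = NULL) {
  set.seed(spec$seed + 1L)
  fit_encoding(features, examples, spec, shuffle_features = TRUE,
               roi = roi, condition = condition, model_name = model_name)
}

#' Representational dissimilarity matrix
#'
#' Word vectors are mean-centred across words (per dimension) and
#' pairwise dissimilarity is computed, by default as one minus the
#' Pearson correlation. Zero-variance word vectors give undefined
#' entries, flagged as NA with a warning.
#'
#' @param features A [feature_matrix()] or words x dimensions matrix with
#'   rownames.
#' @param metric "correlation" (1 - Pearson r, default) or "cosine"
#'   (1 - cosine similarity).
#' @return Object of class `rdm`: symmetric zero-diagonal word x word
#'   matrix plus metadata.
#' @export
compute_rdm <- function(features, metric = c("correlation", "cosine")) {
  metric <- match.arg(metric)
  m <- if (inherits(features, "feature_matrix")) features$matrix
       else as.matrix(features)
  if (nrow(m) < 2L) stop("compute_rdm: need at least 2 words")
  words <- rownames(m)
  mc <- sweep(m, 2L, colMeans(m))
  if (metric == "correlation") {
    sds <- apply(mc, 1L, stats::sd)
    if (any(sds == 0))
      warning("compute_rdm: zero-variance word vector(s); entries set to NA")
    d <- 1 - suppressWarnings(stats::cor(t(mc)))
  } else {
    nrm <- sqrt(rowSums(mc^2))
    if (any(nrm == 0))
      warning("compute_rdm: zero-norm word vector(s); entries set to NA")
    nrm[nrm == 0] <- NA_real_
    d <- 1 - (mc %*% t(mc)) / outer(nrm, nrm)
  }
  diag(d) <- 0
  dimnames(d) <- list(words, words)
  structure(list(model_name = if (inherits(features, "feature_matrix"))
                   features$model_name else NA_character_,
                 matrix = d, metric = metric),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM%s (%s distance): %d words\n",
              if (!is.na(x$model_name)) sprintf(" [%s]", x$model_name) else "",
              x$metric, nrow(x$matrix)))
  invisible(x)
}

#' Compare encoding-model families across subjects
#'
#' Given per-subject aggregate variance explained for several models in
#' two families (word-embedding and computer-vision), computes:
#' (a) a within-family one-way ANOVA per ROI and condition, FDR-corrected
#' over ROIs within each condition; (b) every vision - embedding pairwise
#' difference tested against zero with one-sample t-tests, FDR-corrected;
#' (c) the mean family difference contrasted between deep and shallow per
#' ROI with paired t-tests, FDR-corrected; (d) a bootstrap 95% confidence
#' interval of mean VE per ROI, condition and model.
#'
#' @param results data.frame with columns subject, roi, condition, model,
#'   family ("embedding"/"vision") and ve (one row per cell); the
#'   subject x model grid must be complete.
#' @param q FDR rejection threshold.
#' @param boot_iter Bootstrap iterations for the CIs (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List of data.frames: `anova_within_family`,
#'   `vision_vs_embedding`, `family_condition_contrast`, `ci`.
#' @export
compare_models <- function(results, q = 0.05, boot_iter = 1000,
                           seed = 1L) {
  needed <- c("subject", "roi", "condition", "model", "family", "ve")
  stopifnot(all(needed %in% names(results)))
  grid <- table(results$subject, results$model, results$roi,
                results$condition)
  if (any(grid != 1L)) {
    bad <- which(grid != 1L, arr.ind = TRUE)
    stop("compare_models: unbalanced grid; ", nrow(bad),
         " missing/duplicated cell(s), e.g. subject ",
         dimnames(grid)[[1]][bad[1, 1]], " / model ",
         dimnames(grid)[[2]][bad[1, 2]])
  }

  cells <- split(results, results[c("roi", "condition")], drop = TRUE)

  anova_tab <- do.call(rbind, lapply(cells, function(d) {
    do.call(rbind, lapply(split(d, d$family), function(df) {
      ft <- one_way_anova(split(df$ve, df$model))
      data.frame(roi = d$roi[1], condition = d$condition[1],
                 family = df$family[1], statistic = ft$statistic,
                 df1 = ft$df1, df2 = ft$df2, p = ft$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  anova_tab <- do.call(rbind, lapply(
    split(anova_tab, anova_tab$condition), function(d) {
      f <- fdr_bh(d$p, q = q); d$q <- f$q; d$reject <- f$reject; d
    }))

  pair_tab <- do.call(rbind, lapply(cells, function(d) {
    vis <- unique(d$model[d$family == "vision"])
    emb <- unique(d$model[d$family == "embedding"])
    d <- d[order(d$subject), ]
    do.call(rbind, lapply(vis, function(v) {
      do.call(rbind, lapply(emb, function(e) {
        dv <- d$ve[d$model == v] - d$ve[d$model == e]
        tt <- one_sample_t(dv, mu = 0)
        data.frame(roi = d$roi[1], condition = d$condition[1],
                   vision = v, embedding = e, mean_diff = mean(dv),
                   statistic = tt$statistic, df = tt$df, p = tt$p,
                   effect_direction = sign(mean(dv)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  f <- fdr_bh(pair_tab$p, q = q)
  pair_tab$q <- f$q; pair_tab$reject <- f$reject

  fam_mean <- stats::aggregate(
    ve ~ subject + roi + condition + family, data = results, FUN = mean)
  wide <- stats::reshape(fam_mean, direction = "wide",
                         idvar = c("subject", "roi", "condition"),
                         timevar = "family")
  wide$fdiff <- wide$ve.vision - wide$ve.embedding
  cond_tab <- do.call(rbind, lapply(split(wide, wide$roi), function(d) {
    d <- d[order(d$subject, d$condition), ]
    dd <- d$fdiff[d$condition == "deep"]
    ds <- d$fdiff[d$condition == "shallow"]
    tt <- paired_t(dd, ds)
    data.frame(roi = d$roi[1], statistic = tt$statistic, df = tt$df,
               p = tt$p, effect_direction = sign(mean(dd - ds)),
               stringsAsFactors = FALSE)
  }))
  f <- fdr_bh(cond_tab$p, q = q)
  cond_tab$q <- f$q; cond_tab$reject <- f$reject

  set.seed(seed)
  ci_tab <- do.call(rbind, lapply(
    split(results, results[c("roi", "condition", "model")], drop = TRUE),
    function(d) {
      ci <- bootstrap_ci_mean(d$ve, n_iter = boot_iter)
      data.frame(roi = d$roi[1], condition = d$condition[1],
                 model = d$model[1], mean_ve = mean(d$ve),
                 ci_lower = ci[1], ci_upper = ci[2],
                 stringsAsFactors = FALSE)
    }))
  rownames(anova_tab) <- rownames(pair_tab) <- rownames(cond_tab) <-
    rownames(ci_tab) <- NULL
  list(anova_within_family = anova_tab, vision_vs_embedding = pair_tab,
       family_condition_contrast = cond_tab, ci = ci_tab)
}

#' Positive-voxel counts and overlap between encoding models
#'
#' Per model and subject, counts voxels with positive average variance
#' explained; tests paired count differences between every model pair
#' (FDR-corrected) and reports conditional overlap: of the voxels
#' positive under model A, the fraction also positive under model B and
#' the fraction where B explains more variance.
#'
#' @param results List (per subject) of named lists (per model) of
#'   `encoding_result` objects sharing the voxel grid.
#' @param q FDR rejection threshold.
#' @return List with `counts` (subject x model), `tests` (paired count
#'   differences) and `overlap` (per subject and ordered model pair).
#' @export
positive_voxel_report <- function(results, q = 0.05) {
  models <- names(results[[1]])
  if (length(models) < 2L)
    stop("positive_voxel_report: need >= 2 models")
  counts <- do.call(rbind, lapply(seq_along(results), function(s) {
    vapply(results[[s]], function(r) length(r$positive_voxels), integer(1))
  }))
  rownames(counts) <- names(results)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("subject%d", seq_along(results))

  cmb <- utils::combn(models, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1, k]; b <- cmb[2, k]
    tt <- paired_t(counts[, a], counts[, b])
    data.frame(model_a = a, model_b = b,
               mean_diff = mean(counts[, a] - counts[, b]),
               statistic = tt$statistic, df = tt$df, p = tt$p,
               effect_direction = sign(mean(counts[, a] - counts[, b])),
               stringsAsFactors = FALSE)
  }))
  f <- fdr_bh(tests$p, q = q)
  tests$q <- f$q; tests$reject <- f$reject

  overlap <- do.call(rbind, lapply(seq_along(results), function(s) {
    do.call(rbind, lapply(models, function(a) {
      do.call(rbind, lapply(setdiff(models, a), function(b) {
        ra <- results[[s]][[a]]; rb <- results[[s]][[b]]
        pa <- ra$positive_voxels
        if (!length(pa))
          return(data.frame(subject = rownames(counts)[s], model_a = a,
                            model_b = b, frac_positive_in_b = NA_real_,
                            frac_higher_in_b = NA_real_,
                            stringsAsFactors = FALSE))
        data.frame(
          subject = rownames(counts)[s], model_a = a, model_b = b,
          frac_positive_in_b = mean(rb$voxel_ve[pa] > 0),
          frac_higher_in_b = mean(rb$voxel_ve[pa] > ra$voxel_ve[pa]),
          stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(tests) <- rownames(overlap) <- NULL
  list(counts = counts, tests = tests, overlap = overlap)
}
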