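# trials as an exact (optionally noisy) linear map of word features
encoding_fixture <- function(n_words = 12, reps = 4, n_dims = 30,
                             n_voxels = 8, noise_sd = 0, seed = 1) {
  set.seed(seed)
  gf <- generate_features(paste0("w", seq_len(n_words)), n_dims = n_dims,
                          n_models = 1, voxel_target = n_voxels,
                          fidelity = 1, seed = seed)
  words <- rep(gf$features[[1]]$words, each = reps)
  cats <- rep(rep(c("living", "nonliving"),
                  c(ceiling(n_words / 2), floor(n_words / 2))), each = reps)
  y <- gf$features[[1]]$matrix[words, ] %*% gf$feature_map
  if (noise_sd > 0) y <- y + matrix(rnorm(length(y), sd = noise_sd), nrow(y))
  ex <- trial_examples(y, labels = cats, words = words,
                       run_ids = rep("run01", length(words)))
  list(features = gf$features[[1]], examples = ex, map = gf$feature_map)
}

test_that("a noiseless linear map is recovered with near-perfect variance explained", {
  # few unique word rows in a high-dimensional feature space concentrate
  # the design's spectrum well above the ridge penalty, as in the full
  # design (36 words x 300-D), so shrinkage costs little variance
  fx <- encoding_fixture(n_words = 12, reps = 6, n_dims = 120, noise_sd = 0)
  res <- fit_encoding(fx$features, fx$examples,
                      encoding_spec(alpha = 100, n_folds = 30, seed = 2))
  expect_gt(res$aggregate_ve, 0.9)
  expect_lte(max(res$voxel_ve), 1)
  expect_equal(res$positive_voxels, seq_along(res$voxel_ve))
})

test_that("targets independent of features score at or below zero", {
  fx <- encoding_fixture(seed = 3)
  set.seed(99)
  null_ex <- fx$examples
  null_ex$features <- matrix(rnorm(length(null_ex$features)),
                             nrow(null_ex$features))
  res <- fit_encoding(fx$features, null_ex,
                      encoding_spec(alpha = 100, n_folds = 30, seed = 4))
  expect_lte(mean(res$voxel_ve), 0)
  expect_lte(max(res$voxel_ve), 1)
})

test_that("fold-wise ridge predictions match the closed-form oracle", {
  set.seed(5)
  n <- 10; p <- 4
  x <- matrix(rnorm(n * p), n)
  y <- matrix(rnorm(n), n, 1)
  labels <- rep(c("a", "b"), each = 5)
  ex <- trial_examples(y, labels, paste0("w", 1:n), rep("r", n))
  alpha <- 100
  spec <- encoding_spec(alpha = alpha, n_folds = 5, seed = 6)
  res <- fit_encoding(x, ex, spec)
  # independent oracle: explicit (X'X + aI)^-1 X'y per fold on the same
  # folds (standardized X, centred y), R^2 on the held-out rows
  splits <- make_stratified_splits(labels, n_splits = 5,
                                   test_fraction = 0.2, seed = 6)
  ve <- 0
  for (sp in splits) {
    xt <- x[sp$train, , drop = FALSE]
    mu <- colMeans(xt); sdv <- apply(xt, 2, sd)
    xs <- scale(xt, mu, sdv)
    yc <- y[sp$train, , drop = FALSE] - mean(y[sp$train, ])
    w <- solve(t(xs) %*% xs + alpha * diag(p)) %*% t(xs) %*% yc
    pred <- scale(x[sp$test, , drop = FALSE], mu, sdv) %*% w +
      mean(y[sp$train, ])
    obs <- y[sp$test, ]
    ve <- ve + (1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  }
  expect_equal(res$voxel_ve, ve / 5, tolerance = 1e-8)
})

test_that("variance explained decreases with target noise", {
  ves <- vapply(c(0, 1, 4), function(ns) {
    fx <- encoding_fixture(noise_sd = ns, seed = 7)
    fit_encoding(fx$features, fx$examples,
                 encoding_spec(alpha = 100, n_folds = 20,
                               seed = 8))$aggregate_ve_all
  }, numeric(1))
  expect_true(all(diff(ves) < 0))
})

test_that("the empirical chance shuffle destroys the feature-target mapping", {
  fx <- encoding_fixture(seed = 9)
  spec <- encoding_spec(alpha = 100, n_folds = 20, seed = 10)
  fit <- fit_encoding(fx$features, fx$examples, spec)
  ch <- empirical_chance(fx$features, fx$examples, spec)
  expect_lt(ch$aggregate_ve_all, 0.05)
  expect_lt(ch$aggregate_ve_all, fit$aggregate_ve_all)
  ch2 <- empirical_chance(fx$features, fx$examples, spec)
  expect_identical(ch$voxel_ve, ch2$voxel_ve)  # seed-reproducible
})

test_that("chance variance explained is centred at or below zero under the null", {
  set.seed(11)
  hits <- vapply(1:20, function(s) {
    fx <- encoding_fixture(n_words = 8, reps = 3, n_dims = 10,
                           n_voxels = 3, seed = 100 + s)
    null_ex <- fx$examples
    null_ex$features <- matrix(rnorm(length(null_ex$features)),
                               nrow(null_ex$features))
    empirical_chance(fx$features, null_ex,
                     encoding_spec(alpha = 100, n_folds = 10,
                                   seed = s))$aggregate_ve_all
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.5)
  expect_lte(mean(hits), 0)
})

test_that("RDM matches a brute-force double loop and known limit cases", {
  set.seed(12)
  m <- matrix(rnorm(6 * 20), 6, dimnames = list(paste0("w", 1:6), NULL))
  rdm <- compute_rdm(m)
  mc <- sweep(m, 2, colMeans(m))
  for (i in 1:6) for (j in 1:6) {
    expected <- if (i == j) 0 else 1 - cor(mc[i, ], mc[j, ])
    expect_equal(rdm$matrix[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(rdm$matrix, t(rdm$matrix))
  expect_true(all(diag(rdm$matrix) == 0))

  # anti-proportional vectors: dissimilarity 2
  v <- rnorm(10)
  m2 <- rbind(a = v, b = -2 * v)
  expect_equal(compute_rdm(m2)$matrix["a", "b"], 2, tolerance = 1e-12)

  # identical word vectors become zero-variance after centring: flagged NA
  m3 <- rbind(a = rep(2, 5), b = rep(2, 5))
  expect_warning(r3 <- compute_rdm(m3), "zero-variance")
  expect_true(is.na(r3$matrix["a", "b"]))
})

test_that("RDMs are invariant to per-dimension affine rescaling", {
  set.seed(13)
  m <- matrix(rnorm(8 * 15), 8, dimnames = list(paste0("w", 1:8), NULL))
  shifted <- sweep(m, 2, runif(15, -3, 3), "+")
  r1 <- compute_rdm(m)
  r2 <- compute_rdm(shifted)
  expect_equal(r1$matrix, r2$matrix, tolerance = 1e-10)
})

test_that("model comparison detects a planted vision advantage and interactions", {
  set.seed(14)
  subj <- sprintf("s%02d", 1:10)
  models <- data.frame(
    model = c("vgg", "dense", "mobile", "fasttext", "glove", "word2vec"),
    family = rep(c("vision", "embedding"), each = 3),
    stringsAsFactors = FALSE)
  grid <- expand.grid(subject = subj, roi = c("FFG", "SFG"),
                      condition = c("deep", "shallow"),
                      model = models$model, stringsAsFactors = FALSE)
  grid$family <- models$family[match(grid$model, models$model)]
  base <- ifelse(grid$family == "vision", 0.06, 0.02)
  # interaction: vision advantage larger in deep, FFG only
  base <- base + ifelse(grid$family == "vision" & grid$condition == "deep" &
                          grid$roi == "FFG", 0.05, 0)
  grid$ve <- base + rnorm(nrow(grid), sd = 0.005)
  cm <- compare_models(grid, boot_iter = 200, seed = 1)

  expect_true(all(cm$vision_vs_embedding$mean_diff > 0))
  expect_true(all(cm$vision_vs_embedding$reject))
  cc <- cm$family_condition_contrast
  expect_true(cc$reject[cc$roi == "FFG"])
  expect_false(cc$reject[cc$roi == "SFG"])
  expect_true(all(cm$ci$ci_lower <= cm$ci$mean_ve &
                    cm$ci$mean_ve <= cm$ci$ci_upper))

  # identical data for all models: F ~ 0, no pairwise rejections
  null_grid <- grid
  per_subj <- rnorm(length(subj), 0.05, 0.002)
  null_grid$ve <- per_subj[match(null_grid$subject, subj)]
  cm0 <- compare_models(null_grid, boot_iter = 100, seed = 2)
  expect_true(all(cm0$anova_within_family$statistic < 1e-10))
  expect_false(any(cm0$vision_vs_embedding$reject))

  expect_error(compare_models(grid[-1, ]), "unbalanced")
})

test_that("positive-voxel report counts, tests and overlap behave", {
  set.seed(15)
  mk_res <- function(ve) {
    structure(list(voxel_ve = ve, positive_voxels = which(ve > 0)),
              class = "encoding_result")
  }
  results <- lapply(1:8, function(s) {
    good <- rnorm(30, 0.1, 0.05)   # planted model: mostly positive
    bad <- rnorm(30, -0.05, 0.05)  # noise model: mostly negative
    list(planted = mk_res(good), noise = mk_res(bad))
  })
  rep_ <- positive_voxel_report(results)
  expect_true(all(rep_$counts[, "planted"] > rep_$counts[, "noise"]))
  expect_true(rep_$tests$reject[1])
  expect_true(all(rep_$overlap$frac_positive_in_b >= 0 &
                    rep_$overlap$frac_positive_in_b <= 1, na.rm = TRUE))

  # identical models: zero count difference
  same <- lapply(1:4, function(s) {
    ve <- rnorm(10)
    list(m1 = mk_res(ve), m2 = mk_res(ve))
  })
  rep2 <- positive_voxel_report(same)
  expect_equal(rep2$tests$mean_diff, 0)
  expect_error(positive_voxel_report(lapply(1:3, function(s)
    list(only = mk_res(rnorm(5))))), "2 models")
})
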