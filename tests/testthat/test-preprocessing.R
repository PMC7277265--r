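test_that("invariant voxels are removed with a traceable index map", {
  x <- rbind(rnorm(20), rep(3, 20), rnorm(20))
  run <- bold_run(x, tr = 0.85, run_id = "run01", roi_id = "A")
  out <- remove_invariant_voxels(run)
  expect_equal(out$kept, c(1L, 3L))
  expect_equal(out$run$data, x[c(1, 3), ])

  # no constant voxels: identity
  run2 <- noise_run(5, 30)
  out2 <- remove_invariant_voxels(run2)
  expect_equal(out2$kept, 1:5)

  all_const <- bold_run(matrix(1, 3, 10), 0.85, "run01", "A")
  expect_error(remove_invariant_voxels(all_const), "empty ROI")
})

test_that("per-run scope removes voxels invariant in any single run", {
  set.seed(2)
  r1 <- matrix(rnorm(40), 4); r1[2, ] <- 7   # voxel 2 constant in run 1 only
  r2 <- matrix(rnorm(40), 4)
  runs <- list(bold_run(r1, 0.85, "run01", "A"),
               bold_run(r2, 0.85, "run02", "A"))
  out <- remove_invariant_voxels_runs(runs, scope = "per_run")
  # brute-force oracle: variance scan per run
  bad <- apply(r1, 1, var) == 0 | apply(r2, 1, var) == 0
  expect_equal(out$kept, which(!bad))
  out2 <- remove_invariant_voxels_runs(runs, scope = "stacked")
  expect_equal(out2$kept, 1:4)  # varies across the stack
})

test_that("normalization detrends then z-scores to mean 0 sd 1", {
  set.seed(3)
  x <- matrix(rnorm(6 * 80), 6) + outer(rep(0.5, 6), 1:80)  # slope 0.5/vol
  run <- bold_run(x, 0.85, "run01", "A")
  out <- normalize_runs(list(run))[[1]]
  expect_equal(rowMeans(out$data), rep(0, 6), tolerance = 1e-10)
  expect_equal(apply(out$data, 1, sd), rep(1, 6), tolerance = 1e-10)
  # residual correlation with volume index ~ 0 (explicit regression oracle)
  for (v in 1:6) {
    fit <- lm(x[v, ] ~ seq_len(80))
    oracle <- scale(resid(fit))[, 1] * sqrt(79 / 78)  # sd denominator n-1
    expect_lt(abs(cor(out$data[v, ], seq_len(80))), 1e-10)
    expect_equal(cor(out$data[v, ], oracle), 1, tolerance = 1e-10)
  }
})

test_that("a pure linear trend is zeroed with a warning, not scaled", {
  run <- bold_run(rbind(1:40, rnorm(40)), 0.85, "run01", "A")
  expect_warning(out <- normalize_runs(list(run)), "zero residual variance")
  expect_equal(out[[1]]$data[1, ], rep(0, 40))
  expect_equal(attr(out[[1]], "zeroed"), 1L)
})

test_that("normalization is idempotent on noise data", {
  run <- noise_run(5, 60, seed = 8)
  once <- normalize_runs(list(run))
  twice <- normalize_runs(once)
  expect_lt(max(abs(once[[1]]$data - twice[[1]]$data)), 1e-8)
})

test_that("example window picks six volumes from onset+3.4 s, feature averages five", {
  nvox <- 3; nvol <- 30; tr <- 0.85
  x <- matrix(0, nvox, nvol)
  # encode the volume index so window membership is observable
  for (v in seq_len(nvox)) x[v, ] <- seq_len(nvol)
  run <- bold_run(x, tr, "run01", "A")
  ev <- as_event_table(data.frame(
    onset = 0, duration = 1, word = "tigre", category = "living",
    condition = "deep", run_id = "run01", is_catch = FALSE))
  ex <- extract_trial_examples(list(run), list(ev))
  # onset 0: times >= 3.4 are volumes 5..10 (times 3.4 ... 7.65)
  expect_equal(dim(ex$volume_stack[[1]]), c(3L, 6L))
  expect_equal(ex$volume_stack[[1]][1, ], 5:10)
  # feature = mean of the five volumes with time <= 6.8 (indices 5..9)
  expect_equal(unname(ex$features[1, ]), rep(mean(5:9), 3))
  full <- extract_trial_examples(list(run), list(ev), feature_window = "full")
  expect_equal(unname(full$features[1, ]), rep(mean(5:10), 3))
})

test_that("constant unit window data give unit features", {
  run <- bold_run(matrix(1, 4, 30), 0.85, "run01", "A")
  run$data <- run$data  # constant by construction
  ev <- as_event_table(data.frame(
    onset = 0, duration = 1, word = "w", category = "living",
    condition = "deep", run_id = "run01", is_catch = FALSE))
  ex <- extract_trial_examples(list(run), list(ev))
  expect_equal(unname(ex$features[1, ]), rep(1, 4))
})

test_that("a full default dataset yields 288 balanced examples", {
  cfg <- sim_config(roi_specs = list(roi_spec("A", n_voxels = 10)),
                    seed = 21)
  ds <- generate_dataset(cfg)
  norm <- normalize_runs(ds$bold$A)
  ex <- extract_trial_examples(norm, ds$events)
  expect_equal(nrow(ex$features), 288L)
  expect_equal(unname(table(ex$labels)), c(144L, 144L), ignore_attr = TRUE)
  expect_null(ex$dropped)
})

test_that("trials whose window exceeds the run are dropped with a report", {
  run <- bold_run(matrix(rnorm(3 * 20), 3), 0.85, "run01", "A")
  ev <- as_event_table(data.frame(
    onset = c(0, 14), duration = 1, word = c("a", "b"),
    category = c("living", "nonliving"), condition = "deep",
    run_id = "run01", is_catch = FALSE))
  ex <- extract_trial_examples(list(run), list(ev))
  expect_equal(nrow(ex$features), 1L)
  expect_equal(ex$dropped$word, "b")
})

test_that("windows are invariant to a whole-run volume shift", {
  set.seed(4)
  base <- matrix(rnorm(4 * 60), 4)
  k <- 7  # shift by k volumes
  shifted <- cbind(matrix(rnorm(4 * k), 4), base)
  tr <- 0.85
  ev0 <- as_event_table(data.frame(
    onset = c(2, 20), duration = 1, word = c("a", "b"),
    category = c("living", "nonliving"), condition = "deep",
    run_id = "run01", is_catch = FALSE))
  evk <- ev0; evk$onset <- evk$onset + k * tr
  ex0 <- extract_trial_examples(
    list(bold_run(base, tr, "run01", "A")), list(ev0))
  exk <- extract_trial_examples(
    list(bold_run(shifted, tr, "run01", "A")), list(evk))
  expect_equal(ex0$features, exk$features)
})

test_that("trial volume series partition the run after the first onset", {
  cfg <- sim_config(roi_specs = list(roi_spec("A", n_voxels = 4)), seed = 31)
  ds <- generate_dataset(cfg)
  norm <- normalize_runs(ds$bold$A[1])
  tvs <- extract_trial_volume_series(norm, ds$events[1],
                                     include_catch = TRUE)
  ev <- ds$events[[1]]
  n_before <- sum((seq_len(ncol(norm[[1]]$data)) - 1) * cfg$tr < ev$onset[1])
  expect_equal(sum(tvs$info$n_volumes) + n_before,
               cfg$volumes_per_run - cfg$n_discard)
  # no volume assigned twice: concatenation reproduces the volume order
  expect_equal(do.call(cbind, tvs$series),
               norm[[1]]$data[, (n_before + 1):ncol(norm[[1]]$data)])
})

test_that("two trials twelve volumes apart give a twelve-volume first series", {
  run <- bold_run(matrix(rnorm(2 * 40), 2), 0.85, "run01", "A")
  ev <- as_event_table(data.frame(
    onset = c(0, 12 * 0.85), duration = 1, word = c("a", "b"),
    category = c("living", "nonliving"), condition = "deep",
    run_id = "run01", is_catch = FALSE))
  tvs <- extract_trial_volume_series(list(run), list(ev))
  expect_equal(ncol(tvs$series[[1]]), 12L)
  expect_equal(ncol(tvs$series[[2]]), 40L - 12L)

  tvs1 <- extract_trial_volume_series(list(run), list(ev[1, ]))
  expect_equal(ncol(tvs1$series[[1]]), 40L)  # single trial spans to run end
})
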