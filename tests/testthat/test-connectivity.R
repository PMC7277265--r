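# small simulated ROI with strong category signal for discriminability tests
discrim_fixture <- function(gain = 6, seed = 1, n_voxels = 10) {
  cfg <- tiny_config(
    n_runs = 2, trials_per_run = 8, volumes_per_run = 160,
    rois = list(roi_spec("A", n_voxels = n_voxels,
                         category_gain_deep = gain,
                         category_gain_shallow = gain,
                         word_gain = 0, noise_sd = 0.5,
                         drift_amplitude = 0)),
    seed = seed)
  ds <- generate_dataset(cfg)
  norm <- normalize_runs(ds$bold$A)
  extract_trial_volume_series(norm, ds$events)
}

test_that("discriminability tracks planted signal and sits at chance for noise", {
  tvs <- discrim_fixture(gain = 8, seed = 2)
  dts <- discriminability_timeseries(tvs, roi = "A", condition = "deep")
  expect_length(dts$values, sum(tvs$info$n_volumes))
  expect_true(all(dts$values >= 0 & dts$values <= 1))
  # within the training windows the true class should be detected
  in_window <- unlist(lapply(seq_along(tvs$series), function(t)
    seq_len(ncol(tvs$series[[t]])) %in% tvs$train_cols[[t]]))
  # trial amplitudes are gated by uniform [0,1] multipliers, so weakly
  # gated trials stay near chance; the window mean is still far above it
  expect_gt(mean(dts$values[in_window]), 0.7)
  expect_gt(mean(dts$values[in_window]), mean(dts$values) )

  tvs0 <- discrim_fixture(gain = 0, seed = 3)
  dts0 <- discriminability_timeseries(tvs0)
  expect_equal(mean(dts0$values), 0.5, tolerance = 0.12)
})

test_that("sigmoid-of-decision probability mode is available and bounded", {
  tvs <- discrim_fixture(gain = 4, seed = 4)
  dts <- discriminability_timeseries(
    tvs, classifier_spec(probability_mode = "sigmoid_decision"))
  expect_true(all(dts$values >= 0 & dts$values <= 1))
  expect_gt(sd(dts$values), 0)
})

test_that("informational connectivity is the Pearson matrix of the series", {
  a <- c(0.1, 0.4, 0.6, 0.9)
  b <- c(0.2, 0.3, 0.7, 0.8)
  ic <- informational_connectivity(list(A = a, B = b, C = a))
  # closed-form Pearson oracle on the 4-point pair
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ic$r["A", "B"], oracle, tolerance = 1e-12)
  expect_equal(ic$r["A", "C"], 1)
  expect_equal(ic$r, t(ic$r))
  expect_true(is.na(ic$r["A", "A"]))

  set.seed(5)
  ic0 <- informational_connectivity(list(A = rnorm(10000), B = rnorm(10000)))
  expect_equal(ic0$r["A", "B"], 0, tolerance = 0.05)

  expect_warning(
    icc <- informational_connectivity(list(A = rep(0.5, 5), B = rnorm(5))),
    "constant")
  expect_true(is.na(icc$r["A", "B"]))
  expect_error(informational_connectivity(list(A = 1:3, B = 1:4)),
               "lengths differ")
})

test_that("functional connectivity correlates ROI-mean time courses", {
  set.seed(6)
  shared <- rnorm(80)
  mk <- function(m) list(bold_run(m, 0.85, "run01", "X"))
  rA <- mk(rbind(shared + rnorm(80, sd = 1e-6), shared + rnorm(80, sd = 1e-6)))
  rB <- mk(rbind(shared, shared))
  rC <- mk(rbind(-shared, -shared))
  fc <- functional_connectivity(list(A = rA[[1]], B = rB[[1]], C = rC[[1]]) |>
                                  lapply(list))
  expect_equal(fc$r["A", "B"], 1, tolerance = 1e-6)
  expect_lt(fc$r["A", "C"], 0)
  expect_error(
    functional_connectivity(list(A = list(bold_run(matrix(rnorm(20), 2),
                                                   0.85, "r", "A")),
                                 B = list(bold_run(matrix(rnorm(30), 2),
                                                   0.85, "r", "B")))),
    "scan grid")
})

test_that("permutation effect size separates coupled from independent series", {
  set.seed(8)
  a <- rnorm(500)
  pe_same <- permutation_effect_size(a, a, n_perm = 1000, seed = 1)
  expect_gt(pe_same$effect, 50)
  expect_equal(pe_same$r_true, 1)
  expect_equal(pe_same$null_mean, 0, tolerance = 0.01)
  expect_equal(pe_same$effect,
               (pe_same$r_true - pe_same$null_mean) / pe_same$null_var,
               tolerance = 1e-12)

  effs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    permutation_effect_size(rnorm(300), rnorm(300), n_perm = 500,
                            seed = s)$effect
  }, numeric(1))
  # independent series: effect fluctuates around 0 at null scale
  expect_lt(abs(mean(effs)), 150)  # null sd of effect ~ n, mean ~ 0
  expect_gt(pe_same$effect, max(abs(effs)))

  pe <- permutation_effect_size(a, a, n_perm = 200, seed = 2)
  pe2 <- permutation_effect_size(a, a, n_perm = 200, seed = 2)
  expect_identical(pe$effect, pe2$effect)
  expect_error(permutation_effect_size(rep(1, 10), rnorm(10)), "constant")
  expect_warning(permutation_effect_size(rnorm(10), rnorm(10), n_perm = 50),
                 "100")
})

test_that("condition contrast flags only pairs with a planted difference", {
  set.seed(9)
  n_subj <- 12
  rois <- c("A", "B", "C")
  mk <- function(ab) {
    m <- diag(3) * NA
    m[lower.tri(m)] <- rnorm(3, sd = 0.05)
    m[1, 2] <- m[2, 1] <- ab + rnorm(1, sd = 0.05)
    m[1, 3] <- m[3, 1] <- rnorm(1, sd = 0.05)
    m[2, 3] <- m[3, 2] <- rnorm(1, sd = 0.05)
    dimnames(m) <- list(rois, rois)
    m
  }
  deep <- lapply(seq_len(n_subj), function(i) mk(0.5))
  shallow <- lapply(seq_len(n_subj), function(i) mk(0))
  st <- condition_contrast(deep, shallow)
  expect_equal(nrow(st), 3L)  # 3 ROIs -> 3 pairs
  ab <- st[st$roi_a == "A" & st$roi_b == "B", ]
  expect_true(ab$reject)
  expect_equal(ab$effect_direction, 1)
  expect_false(any(st$reject[!(st$roi_a == "A" & st$roi_b == "B")]))

  # identical matrices: all t = 0, nothing rejected
  st0 <- condition_contrast(deep, deep)
  expect_true(all(st0$statistic == 0))
  expect_false(any(st0$reject))

  # 15 ROIs -> 105 tested pairs
  big <- matrix(rnorm(225), 15); big <- (big + t(big)) / 2
  deep15 <- lapply(1:4, function(i) big + matrix(rnorm(225, sd = 1e-3), 15))
  st15 <- condition_contrast(deep15, deep15)
  expect_equal(nrow(st15), 105L)
})
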