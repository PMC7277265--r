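# Small simulation configurations used across the suite. Sizes are chosen
# so every stage (schedule, HRF convolution, LOO discriminability) runs in
# well under a second while preserving the design's structure.

tiny_config <- function(n_runs = 2, trials_per_run = 8,
                        volumes_per_run = 160, rois = NULL,
                        coupling = list(), seed = 1L, ...) {
  if (is.null(rois))
    rois <- list(roi_spec("A", n_voxels = 12))
  sim_config(n_runs = n_runs, trials_per_run = trials_per_run,
             n_words_per_category = trials_per_run %/% 2L,
             volumes_per_run = volumes_per_run,
             roi_specs = rois, coupling = coupling, seed = seed, ...)
}

# examples with two planted Gaussian classes separated along a pattern
separable_examples <- function(n_per_class = 12, n_voxels = 10, sep = 4,
                               seed = 1L) {
  set.seed(seed)
  pattern <- rnorm(n_voxels)
  pattern <- pattern / sqrt(sum(pattern^2))
  x <- rbind(
    matrix(rnorm(n_per_class * n_voxels), n_per_class) +
      sep / 2 * matrix(pattern, n_per_class, n_voxels, byrow = TRUE),
    matrix(rnorm(n_per_class * n_voxels), n_per_class) -
      sep / 2 * matrix(pattern, n_per_class, n_voxels, byrow = TRUE))
  trial_examples(
    x, labels = rep(c("living", "nonliving"), each = n_per_class),
    words = paste0("w", seq_len(2 * n_per_class)),
    run_ids = rep(c("run01", "run02"), n_per_class))
}

# noise-only bold run on the post-discard grid
noise_run <- function(n_voxels = 8, n_volumes = 100, tr = 0.85,
                      run_id = "run01", roi_id = "A", seed = 1L) {
  set.seed(seed)
  bold_run(matrix(rnorm(n_voxels * n_volumes), n_voxels), tr = tr,
           run_id = run_id, roi_id = roi_id, n_discarded = 0L)
}
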