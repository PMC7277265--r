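#' Feature matrix container
#'
#' Word-level feature representations (e.g. 300-D word-embedding or
#' computer-vision vectors), one row per word.
#'
#' @param matrix words x dimensions numeric matrix with rownames = words.
#' @param model_name Label.
#' @param family "embedding" or "vision".
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(matrix, model_name,
                           family = c("embedding", "vision")) {
  family <- match.arg(family)
  matrix <- as.matrix(matrix)
  if (any(!is.finite(matrix)))
    stop("feature_matrix: non-finite entries")
  if (is.null(rownames(matrix)))
    stop("feature_matrix: rownames must give the words")
  structure(list(model_name = model_name, family = family,
                 matrix = matrix, words = rownames(matrix)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix '%s' (%s): %d words x %d dimensions\n",
              x$model_name, x$family, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Generate synthetic word-feature matrices with known structure
#'
#' Builds `n_models` word-by-dimension feature matrices as
#' `fidelity * shared latent + (1 - fidelity) * model-specific noise`.
#' The shared latent structure carries a planted category separation
#' (living vs non-living mean offset), so representational analyses have a
#' recoverable signal; at fidelity 1 all models are identical, at fidelity
#' 0 they are independent. A random linear map from the first model's
#' feature space into a target voxel space is returned so that
#' encoding-model recovery is testable against ground truth.
#'
#' @param word_list Character vector of distinct words.
#' @param n_dims Feature dimensionality (default 300).
#' @param n_models Number of matrices to generate.
#' @param voxel_target Number of voxels the returned linear map projects
#'   into (or a [roi_spec()], whose `n_voxels` is used).
#' @param fidelity Value in [0, 1]: weight of the shared latent structure.
#' @param categories Optional category per word ("living"/"nonliving");
#'   default: first half living, second half non-living.
#' @param category_separation Mean offset between the categories in latent
#'   space, in units of the latent sd (default 1).
#' @param model_names,families Optional labels per model.
#' @param seed Optional integer seed.
#' @return List with `features` (list of [feature_matrix()]) and
#'   `feature_map` (n_dims x n_voxels matrix mapping model 1's features to
#'   voxel responses).
#' @export
generate_features <- function(word_list, n_dims = 300, n_models = 2,
                              voxel_target = 20, fidelity = 1,
                              categories = NULL, category_separation = 1,
                              model_names = NULL, families = NULL,
                              seed = NULL) {
  if (anyDuplicated(word_list))
    stop("generate_features: words must be distinct")
  if (n_dims < 1) stop("generate_features: 'n_dims' must be >= 1")
  if (fidelity < 0 || fidelity > 1)
    stop("generate_features: 'fidelity' must lie in [0, 1]")
  if (inherits(voxel_target, "roi_spec")) voxel_target <- voxel_target$n_voxels
  n_w <- length(word_list)
  if (is.null(categories))
    categories <- rep(c("living", "nonliving"),
                      c(ceiling(n_w / 2), floor(n_w / 2)))
  if (!is.null(seed)) set.seed(seed)

  mu <- matrix(stats::rnorm(2 * n_dims, sd = category_separation / 2),
               2, n_dims, dimnames = list(c("living", "nonliving"), NULL))
  mu["nonliving", ] <- -mu["living", ]
  latent <- mu[categories, , drop = FALSE] +
    matrix(stats::rnorm(n_w * n_dims), n_w, n_dims)
  rownames(latent) <- word_list

  if (is.null(model_names))
    model_names <- sprintf("model%d", seq_len(n_models))
  if (is.null(families))
    families <- rep("embedding", n_models)
  feats <- lapply(seq_len(n_models), function(m) {
    noise <- matrix(stats::rnorm(n_w * n_dims), n_w, n_dims,
                    dimnames = list(word_list, NULL))
    feature_matrix(fidelity * latent + (1 - fidelity) * noise,
                   model_name = model_names[m], family = families[m])
  })
  fmap <- matrix(stats::rnorm(n_dims * voxel_target, sd = 1 / sqrt(n_dims)),
                 n_dims, voxel_target)
  list(features = feats, feature_map = fmap)
}
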