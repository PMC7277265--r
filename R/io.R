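#' Write trial events as a BIDS-style TSV
#'
#' Tab-delimited, UTF-8, '.' decimal; columns onset, duration,
#' trial_type ("word"/"catch"), word, category, condition, run,
#' is_catch.
#'
#' @param events An `event_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(
    onset = events$onset, duration = events$duration,
    trial_type = ifelse(events$is_catch, "catch", "word"),
    word = events$word,
    category = ifelse(is.na(events$category), "n/a", events$category),
    condition = events$condition, run = events$run_id,
    is_catch = as.integer(events$is_catch), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' Validates the schema (required columns, strictly increasing onsets
#' per run, word/category consistency) and reports violations with
#' row/column context.
#'
#' @param path TSV file path.
#' @return An `event_table`.
#' @export
read_events_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("onset", "duration", "word", "category", "condition",
              "run", "is_catch")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("read_events_tsv: '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  for (r in unique(x$run)) {
    o <- x$onset[x$run == r]
    bad <- which(diff(o) <= 0)
    if (length(bad))
      stop(sprintf(
        "read_events_tsv: onsets not strictly increasing in run '%s' at row %d",
        r, bad[1] + 1L))
  }
  ev <- data.frame(
    onset = as.numeric(x$onset), duration = as.numeric(x$duration),
    word = x$word,
    category = ifelse(x$category %in% c("n/a", "NA", ""), NA_character_,
                      x$category),
    condition = x$condition, run_id = as.character(x$run),
    is_catch = as.logical(as.integer(x$is_catch)),
    stringsAsFactors = FALSE)
  as_event_table(ev)
}

#' Write a simulated dataset to disk
#'
#' BOLD data are written one 4D NIfTI per run, with all ROIs' voxels
#' stacked on the first axis (identity affine, documented here: voxel v
#' of ROI r sits at x-index offset(r) + v); each ROI's binary mask is a
#' 3D NIfTI on the same grid; events go to per-run BIDS-style TSVs, the
#' ground truth and the layout to JSON. Doubles are stored at full
#' precision.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rois <- names(dataset$bold)
  nvox <- vapply(rois, function(r) nrow(dataset$bold[[r]][[1]]$data),
                 integer(1))
  offset <- c(0L, cumsum(nvox))[seq_along(rois)]
  names(offset) <- rois
  total <- sum(nvox)
  n_runs <- length(dataset$events)

  for (r in rois) {
    mask <- array(0L, dim = c(total, 1L, 1L))
    mask[offset[[r]] + seq_len(nvox[[r]]), 1L, 1L] <- 1L
    RNifti::writeNifti(RNifti::asNifti(mask, datatype = "int16"),
                       file.path(dir, sprintf("mask_%s.nii.gz", r)))
  }
  tr <- dataset$bold[[1]][[1]]$tr
  for (i in seq_len(n_runs)) {
    nvol <- ncol(dataset$bold[[1]][[i]]$data)
    vol <- array(0, dim = c(total, 1L, 1L, nvol))
    for (r in rois)
      vol[offset[[r]] + seq_len(nvox[[r]]), 1L, 1L, ] <-
        dataset$bold[[r]][[i]]$data
    img <- RNifti::asNifti(vol, datatype = "double")
    RNifti::writeNifti(img, file.path(dir, sprintf("bold_run%02d.nii.gz", i)))
    write_events_tsv(dataset$events[[i]],
                     file.path(dir, sprintf("events_run%02d.tsv", i)))
  }
  gt <- dataset$ground_truth
  meta <- list(
    rois = as.list(stats::setNames(as.integer(nvox), rois)),
    tr = tr, n_runs = n_runs,
    n_discarded = dataset$bold[[1]][[1]]$n_discarded,
    coupling_pairs = gt$coupling_pairs)
  jsonlite::write_json(meta, file.path(dir, "layout.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(category_patterns = gt$category_patterns,
         word_patterns = gt$word_patterns,
         gating_series = gt$gating_series),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Voxels inside each mask are taken in ascending linear index order of
#' the mask grid.
#'
#' @param dir Dataset directory.
#' @return List with `bold`, `events`, `masks` as in
#'   [generate_dataset()] (ground truth is reloaded as plain lists under
#'   `ground_truth` when present).
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "layout.json"),
                              simplifyVector = TRUE)
  rois <- names(meta$rois)
  masks_idx <- lapply(rois, function(r) {
    m <- RNifti::readNifti(file.path(dir, sprintf("mask_%s.nii.gz", r)))
    which(as.vector(m) > 0)
  })
  names(masks_idx) <- rois
  events <- lapply(seq_len(meta$n_runs), function(i)
    read_events_tsv(file.path(dir, sprintf("events_run%02d.tsv", i))))
  bold <- lapply(rois, function(r) {
    lapply(seq_len(meta$n_runs), function(i) {
      img <- RNifti::readNifti(file.path(dir, sprintf("bold_run%02d.nii.gz", i)))
      d <- dim(img)
      flat <- matrix(as.vector(img), prod(d[1:3]), d[4])
      bold_run(flat[masks_idx[[r]], , drop = FALSE], tr = meta$tr,
               run_id = events[[i]]$run_id[1], roi_id = r,
               n_discarded = meta$n_discarded)
    })
  })
  names(bold) <- rois
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(bold = bold, events = events,
       masks = vapply(masks_idx, length, integer(1)),
       ground_truth = gt)
}

#' Read a word-feature CSV
#'
#' First column = word, remaining columns = feature dimensions.
#'
#' @param path CSV file path.
#' @param model_name Label (default: file name without extension).
#' @param family "embedding" or "vision".
#' @return A [feature_matrix()].
#' @export
read_features_csv <- function(path, model_name = NULL,
                              family = c("embedding", "vision")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2L)
    stop("read_features_csv: need a word column plus >= 1 dimension")
  if (anyDuplicated(x[[1]]))
    stop("read_features_csv: duplicate words in column 1")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x[[1]]
  if (is.null(model_name))
    model_name <- sub("\\.[^.]*$", "", basename(path))
  feature_matrix(m, model_name = model_name, family = match.arg(family))
}

#' Write a word-feature matrix as CSV
#'
#' @param features A [feature_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  out <- data.frame(word = features$words, features$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write trial examples with a sidecar label TSV
#'
#' The trial-by-voxel matrix goes to `<stem>_features.tsv`, the labels
#' (category, word, run, condition) to `<stem>_labels.tsv`.
#'
#' @param examples A [trial_examples()].
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_trial_examples <- function(examples, stem) {
  utils::write.table(examples$features,
                     paste0(stem, "_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(category = examples$labels, word = examples$words,
               run = examples$run_ids, condition = examples$conditions,
               stringsAsFactors = FALSE),
    paste0(stem, "_labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(stem)
}

#' Read trial examples written by [write_trial_examples()]
#'
#' @param stem Path stem used when writing.
#' @return A [trial_examples()].
#' @export
read_trial_examples <- function(stem) {
  feats <- as.matrix(utils::read.table(paste0(stem, "_features.tsv"),
                                       sep = "\t", header = FALSE))
  labs <- utils::read.table(paste0(stem, "_labels.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  trial_examples(feats, labs$category, labs$word, labs$run,
                 labs$condition)
}

#' Run the full single-subject pipeline on simulated data
#'
#' Generates a dataset from `config`, preprocesses every ROI (invariant
#' voxel removal, run-wise detrend + z-score, trial-example extraction)
#' and decodes the word category per ROI and condition with the
#' stratified-shuffle PCA + SVM pipeline.
#'
#' @param config A [sim_config()].
#' @param n_splits Stratified splits per ROI x condition.
#' @param spec A [classifier_spec()].
#' @param seed Seed for the split generator.
#' @return List with `accuracy` (tidy data.frame: roi, condition, scheme,
#'   mean_accuracy), `examples` (per ROI), `results` (decoding_result
#'   objects), `dataset`.
#' @export
run_subject <- function(config, n_splits = 50, spec = classifier_spec(),
                        seed = 1L) {
  dataset <- generate_dataset(config)
  rois <- names(dataset$bold)
  examples <- list(); results <- list(); rows <- list()
  for (r in rois) {
    cleaned <- remove_invariant_voxels_runs(dataset$bold[[r]])
    norm <- suppressWarnings(normalize_runs(cleaned$runs))
    ex <- extract_trial_examples(norm, dataset$events)
    examples[[r]] <- ex
    for (cond in unique(ex$conditions)) {
      sub <- subset_examples(ex, ex$conditions == cond)
      splits <- make_stratified_splits(sub$labels, n_splits = n_splits,
                                       seed = seed)
      res <- decode(sub, splits, spec, roi = r, condition = cond)
      results[[paste(r, cond, sep = ".")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, condition = cond, scheme = res$scheme,
        mean_accuracy = res$mean_accuracy, stringsAsFactors = FALSE)
    }
  }
  list(accuracy = do.call(rbind, rows), examples = examples,
       results = results, dataset = dataset)
}
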