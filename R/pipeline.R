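#' Run the structure-centric pipeline on one image
#'
#' Convenience wrapper chaining the stages: RGB to HSV, k-means color
#' reduction, cluster-to-structure assignment (from a file-style assignment
#' or automatically from a ground-truth raster), cascade training and
#' pixel classification.
#'
#' @param image `H x W x 3` RGB raster in `[0, 1]`.
#' @param assignment a `color_assignment`, or `NULL` to derive one from
#'   `truth` via [auto_assign()].
#' @param truth ground-truth class raster (required when `assignment` is
#'   `NULL`).
#' @param k color clusters (default 10).
#' @param C SVM box constraint (default 1).
#' @param purity_threshold [auto_assign()] threshold (default 0.9).
#' @param seed RNG seed for clustering and training subsampling.
#' @param max_per_class see [train_cascade()].
#' @return list with elements `hsv`, `clustered`, `assignment`, `cascade`,
#'   `classified` and `means` (the per-structure HSV means).
#' @export
process_image <- function(image, assignment = NULL, truth = NULL, k = 10L,
                          C = 1, purity_threshold = 0.9, seed = 1L,
                          max_per_class = 2000L) {
  hsv <- rgb_to_hsv(image)
  clustered <- reduce_colors(hsv, k = k, seed = seed)
  if (is.null(assignment)) {
    if (is.null(truth))
      stop("either an assignment or a ground-truth raster is required",
           call. = FALSE)
    assignment <- auto_assign(clustered, truth, purity_threshold)
  }
  training <- build_training_set(clustered, assignment)
  cascade <- train_cascade(training, C = C, max_per_class = max_per_class,
                           seed = seed)
  classified <- classify_image(cascade, hsv)
  list(hsv = hsv, clustered = clustered, assignment = assignment,
       cascade = cascade, classified = classified,
       means = structure_means(hsv, classified))
}

#' Normalize a cohort of images against shared targets
#'
#' Runs [process_image()] on every tile, derives target colors as the
#' cohort's per-structure mean colors (unless targets are supplied),
#' normalizes each image, and reports the inter-image variability of
#' structure means before and after.
#'
#' @param cohort list of tiles, each a list with `image` (RGB raster) and
#'   optionally `labels` (ground-truth raster, used for auto-assignment).
#' @param targets 4 x 3 HSV target matrix, or `NULL` to derive from the
#'   cohort.
#' @param seed master seed; per-image child seeds are drawn from it.
#' @inheritParams process_image
#' @return list with `processed` (per-image [process_image()] results),
#'   `targets`, `normalized` (per-image HSV rasters), `pre`, `post`
#'   (variability tables) and `report` (a [variability_report()]).
#' @export
normalize_cohort <- function(cohort, targets = NULL, k = 10L, C = 1,
                             purity_threshold = 0.9, seed = 1L,
                             max_per_class = 2000L) {
  stopifnot(length(cohort) >= 2L)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, length(cohort))
  processed <- lapply(seq_along(cohort), function(i)
    process_image(cohort[[i]]$image, truth = cohort[[i]]$labels, k = k,
                  C = C, purity_threshold = purity_threshold,
                  seed = child[i], max_per_class = max_per_class))
  pairs <- lapply(processed, function(p)
    list(image = p$hsv, classified = p$classified))
  if (is.null(targets)) targets <- derive_targets(pairs)
  normalized <- lapply(processed, function(p)
    normalize_image(p$hsv, p$classified, targets))
  post_pairs <- lapply(seq_along(processed), function(i)
    list(image = normalized[[i]], classified = processed[[i]]$classified))
  pre <- inter_image_variability(pairs)
  post <- inter_image_variability(post_pairs)
  list(processed = processed, targets = targets, normalized = normalized,
       pre = pre, post = post, report = variability_report(pre, post))
}
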