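# accept a classified_image or a bare integer class raster
as_class_map <- function(classified) {
  if (inherits(classified, "classified_image")) classified$class_map
  else if (is.matrix(classified)) classified
  else stop("expected a classified_image or an integer class raster",
            call. = FALSE)
}

validate_targets <- function(targets) {
  if (!is.matrix(targets) || any(dim(targets) != c(4L, 3L)) ||
      !setequal(rownames(targets), tissue_classes()))
    stop("targets must be a 4 x 3 matrix with rows named by tissue class",
         call. = FALSE)
  fin <- is.finite(targets)
  if (any(targets[fin] < 0) || any(targets[fin] > 1))
    stop("target components must lie in [0, 1]", call. = FALSE)
  if (isTRUE(targets["white", "s"] > 0.1))
    warning("white target saturation ", round(targets["white", "s"], 3),
            " is not near 0; white/lumen should be nearly achromatic")
  invisible(targets)
}

#' Per-structure mean colors of an image
#'
#' Saturation and value are arithmetic means; hue is a circular mean
#' (resultant vector), so hues straddling the red wrap average correctly.
#'
#' @param image HSV raster.
#' @param classified a [classify_image()] result (or an integer class
#'   raster) aligned with `image`.
#' @return 4 x 3 matrix (rows `white, stroma, nuclei, cytoplasm`, columns
#'   `h, s, v`); a class with no pixels yields an `NA` row with a warning.
#' @export
structure_means <- function(image, classified) {
  d <- raster_dim(image)
  if (prod(d) == 0) stop("empty image", call. = FALSE)
  cm <- as_class_map(classified)
  if (!all(dim(cm) == d[1:2]))
    stop("class map does not align with the image", call. = FALSE)
  m <- channel_matrix(image)
  cls <- as.vector(cm)
  out <- matrix(NA_real_, 4L, 3L,
                dimnames = list(tissue_classes(), c("h", "s", "v")))
  for (c in 1:4) {
    sel <- cls == c
    if (!any(sel)) {
      warning("class ", tissue_classes()[c],
              " has no pixels; mean reported as NA")
      next
    }
    out[c, ] <- c(circ_mean01(m[sel, 1]), mean(m[sel, 2]), mean(m[sel, 3]))
  }
  out
}

#' Derive target colors from a set of classified images
#'
#' The target for each structure is the mean over images of the per-image
#' structure means (circular in hue).  The choice of target is arbitrary in
#' principle — any valid 4 x 3 HSV matrix may be passed to
#' [normalize_image()] instead.
#'
#' @param images list of pairs, each a list with elements `image` (HSV
#'   raster) and `classified`.
#' @return 4 x 3 HSV target matrix.
#' @export
derive_targets <- function(images) {
  if (!length(images)) stop("empty image list", call. = FALSE)
  means <- lapply(images, function(p) structure_means(p$image, p$classified))
  out <- matrix(NA_real_, 4L, 3L,
                dimnames = list(tissue_classes(), c("h", "s", "v")))
  for (c in 1:4) {
    rows <- do.call(rbind, lapply(means, function(m) m[c, ]))
    rows <- rows[stats::complete.cases(rows), , drop = FALSE]
    if (!nrow(rows))
      stop("class ", tissue_classes()[c], " is absent from every image",
           call. = FALSE)
    out[c, ] <- c(circ_mean01(rows[, 1]), mean(rows[, 2]), mean(rows[, 3]))
  }
  validate_targets(out)
  out
}

#' Remap an image onto target colors, preserving per-pixel deviation
#'
#' The three-step normalization: (1) measure each pixel's deviation
#' `Δd` about the mean color of its tissue structure in its own image,
#' per HSV channel (hue circularly); (2) remap the pixel to the target
#' color of its class and modulate it by `Δd`; (3) constrain the result to
#' `[0, 1]` — saturation and value are clipped, hue is wrapped modulo 1 by
#' default since it is circular (set `hue_clip = TRUE` to clip it instead).
#'
#' For unclipped pixels the deviation about the structure mean is exactly
#' conserved, so each structure's mean color lands on its target while the
#' within-structure modulation of the original image survives.
#'
#' @param image HSV raster.
#' @param classified aligned classification.
#' @param targets 4 x 3 HSV target matrix (e.g. [derive_targets()]).
#' @param hue_clip clip hue to `[0, 1]` instead of wrapping (default
#'   `FALSE`).
#' @return normalized HSV raster.
#' @export
normalize_image <- function(image, classified, targets, hue_clip = FALSE) {
  d <- raster_dim(image)
  validate_targets(targets)
  cm <- as_class_map(classified)
  means <- suppressWarnings(structure_means(image, cm))
  m <- channel_matrix(image)
  cls <- as.vector(cm)
  out <- m
  for (c in 1:4) {
    sel <- cls == c
    if (!any(sel)) next
    if (any(!is.finite(targets[c, ])) || any(!is.finite(means[c, ]))) {
      warning("class ", tissue_classes()[c],
              " lacks a target or a structure mean; pixels passed through")
      next
    }
    dh <- circ_diff01(m[sel, 1], means[c, "h"])
    h <- targets[c, "h"] + dh
    out[sel, 1] <- if (hue_clip) clamp01(h) else wrap01(h)
    out[sel, 2] <- clamp01(targets[c, "s"] + (m[sel, 2] - means[c, "s"]))
    out[sel, 3] <- clamp01(targets[c, "v"] + (m[sel, 3] - means[c, "v"]))
  }
  channel_array(out, d)
}

#' Flat class-target mapping (no deviation term)
#'
#' Maps every pixel to its class target color with no per-pixel
#' modulation.  This is the control for measuring how much image detail
#' the deviation term preserves: its output holds at most four distinct
#' colors.
#'
#' @inheritParams normalize_image
#' @return HSV raster with at most four distinct colors.
#' @export
normalize_without_deviation <- function(image, classified, targets) {
  d <- raster_dim(image)
  validate_targets(targets)
  cm <- as_class_map(classified)
  cls <- as.vector(cm)
  out <- targets[cls, , drop = FALSE]
  channel_array(out, d)
}
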