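# fit one linear soft-margin SVM stage and extract its hyperplane.
# decision(x) = x . w + b, oriented so the "positive" side is the class
# named first at that stage of the cascade.
fit_stage <- function(x, positive, C) {
  if (!any(positive) || all(positive))
    stop("a cascade stage needs training points on both sides",
         call. = FALSE)
  y <- factor(ifelse(positive, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  w <- unname(drop(crossprod(fit$SV, fit$coefs)))
  b <- -fit$rho
  d <- drop(x %*% w) + b
  if (mean(d[positive]) < mean(d[!positive])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b, wnorm = sqrt(sum(w^2)))
}

stage_distance <- function(stage, x) {
  (drop(x %*% stage$w) + stage$b) / stage$wnorm
}

#' Train the three-stage linear-SVM decision tree
#'
#' Three soft-margin linear SVMs (box constraint `C`, default 1) arranged
#' as a cascade over Cartesian-HSV color points: stage 1 separates
#' white/lumen from tissue, stage 2 stroma from putative epithelium
#' (white points excluded), stage 3 nuclei from cytoplasm (only those two
#' classes).
#'
#' Very large training sets are subsampled per class (seeded) before
#' fitting: the hyperplanes are estimated from a color distribution that a
#' few thousand pixels per class already characterize, and the SVM solver
#' scales superlinearly in the number of points.
#'
#' @param training a [build_training_set()] result (all four classes
#'   present).
#' @param C soft-margin box constraint, `> 0` (default 1).
#' @param max_per_class per-class training-point cap (default 2000);
#'   `Inf` disables subsampling.
#' @param seed RNG seed for the subsampling draw.
#' @return object of class `cascade_classifier` with one `(w, b, |w|)`
#'   hyperplane per stage.
#' @export
train_cascade <- function(training, C = 1, max_per_class = 2000L, seed = 1L) {
  stopifnot(inherits(training, "training_set"))
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  x <- training$x
  y <- training$y
  if (any(table(y) == 0))
    stop("all four tissue classes must be present in training",
         call. = FALSE)
  if (is.finite(max_per_class)) {
    set.seed(seed)
    keep <- unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      if (length(i) > max_per_class) sample(i, max_per_class) else i
    }), use.names = FALSE)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  s1 <- fit_stage(x, y == "white", C)
  t2 <- y != "white"
  s2 <- fit_stage(x[t2, , drop = FALSE], y[t2] == "stroma", C)
  t3 <- y %in% c("nuclei", "cytoplasm")
  s3 <- fit_stage(x[t3, , drop = FALSE], y[t3] == "nuclei", C)
  structure(list(stages = list(white = s1, stroma = s2, nuclei = s3), C = C),
            class = "cascade_classifier")
}

#' @export
print.cascade_classifier <- function(x, ...) {
  cat("cascade_classifier (linear SVM decision tree, C =", x$C, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  stage %-6s  w = (% .3f, % .3f, % .3f)  b = % .3f\n",
                nm, x$stages[[nm]]$w[1] / x$stages[[nm]]$wnorm,
                x$stages[[nm]]$w[2] / x$stages[[nm]]$wnorm,
                x$stages[[nm]]$w[3] / x$stages[[nm]]$wnorm,
                x$stages[[nm]]$b / x$stages[[nm]]$wnorm))
  invisible(x)
}

#' Classify every pixel and record signed-distance certainty
#'
#' Each pixel's Cartesian color point is routed through the decision tree;
#' distances are geometric (divided by `|w|`) so they are comparable across
#' stages and invariant to rescaling of `w`.  The result carries a
#' four-channel structure: the winning class channel holds the positive
#' distance to the hyperplane that decided the class, and every other
#' channel holds the negative distance to the hyperplane at which that
#' class's branch was rejected.  Negative values therefore indicate a low
#' likelihood that the pixel belongs to that class; the unique nonnegative
#' channel (equivalently the signed argmax) recovers the class map.
#' Pixels at distance exactly 0 are routed to the positive (first-named)
#' branch.
#'
#' @param cascade a trained [train_cascade()] classifier.
#' @param image HSV raster.
#' @return object of class `classified_image`: `class_map` (`H x W`
#'   integers 1..4 in [tissue_classes()] order), `certainty`
#'   (`H x W x 4` signed distances), `stage_distance` (`H x W`, the
#'   absolute distance at the deciding stage).
#' @export
classify_image <- function(cascade, image) {
  stopifnot(inherits(cascade, "cascade_classifier"))
  d <- raster_dim(image)
  x <- channel_matrix(hsv_to_cartesian(image))
  d1 <- stage_distance(cascade$stages$white, x)
  d2 <- stage_distance(cascade$stages$stroma, x)
  d3 <- stage_distance(cascade$stages$nuclei, x)
  white <- d1 >= 0
  stroma <- !white & d2 >= 0
  epith <- !white & !stroma
  nuclei <- epith & d3 >= 0
  cyto <- epith & !nuclei
  cls <- integer(nrow(x))
  cls[white] <- 1L
  cls[stroma] <- 2L
  cls[nuclei] <- 3L
  cls[cyto] <- 4L
  cert <- cbind(
    white     = d1,
    stroma    = ifelse(white, -d1, d2),
    nuclei    = ifelse(white, -d1, ifelse(stroma, -d2, d3)),
    cytoplasm = ifelse(white, -d1, ifelse(stroma, -d2, -d3))
  )
  deciding <- abs(ifelse(white, d1, ifelse(stroma, d2, d3)))
  structure(list(
    class_map = matrix(cls, d[1], d[2]),
    certainty = array(cert, dim = c(d[1], d[2], 4L),
                      dimnames = list(NULL, NULL, tissue_classes())),
    stage_distance = matrix(deciding, d[1], d[2])
  ), class = "classified_image")
}

#' @export
print.classified_image <- function(x, ...) {
  frac <- table(factor(tissue_classes()[x$class_map],
                       levels = tissue_classes())) / length(x$class_map)
  cat("classified_image: ", nrow(x$class_map), "x", ncol(x$class_map),
      " pixels\n", sep = "")
  print(round(frac, 3))
  invisible(x)
}

#' Per-class certainty rasters for visualization
#'
#' For each class, the absolute certainty of pixels assigned to it, scaled
#' to `[0, 1]` by that class's per-image maximum, zero elsewhere —
#' the certainty-modulated class map rendering.
#'
#' @param classified a [classify_image()] result.
#' @return named list of four `H x W` rasters in `[0, 1]`.
#' @export
render_certainty <- function(classified) {
  stopifnot(inherits(classified, "classified_image"))
  out <- lapply(seq_along(tissue_classes()), function(c) {
    m <- abs(classified$certainty[, , c])
    m[classified$class_map != c] <- 0
    mx <- max(m)
    if (mx == 0) {
      warning("all-zero certainty for class ", tissue_classes()[c])
      return(m)
    }
    m / mx
  })
  names(out) <- tissue_classes()
  out
}
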