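# farthest-point ("maximin") seeding: first center random, each further
# center the point with maximal distance to its nearest chosen center
farthest_point_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- (x[, 1] - x[idx[1], 1])^2 + (x[, 2] - x[idx[1], 2])^2 +
      (x[, 3] - x[idx[1], 3])^2
    for (j in 2:k) {
      idx[j] <- which.max(d2)
      nd <- (x[, 1] - x[idx[j], 1])^2 + (x[, 2] - x[idx[j], 2])^2 +
        (x[, 3] - x[idx[j], 3])^2
      d2 <- pmin(d2, nd)
    }
  }
  x[idx, , drop = FALSE]
}

nearest_center <- function(x, centers) {
  n <- nrow(x)
  best <- rep.int(1L, n)
  bestd <- (x[, 1] - centers[1, 1])^2 + (x[, 2] - centers[1, 2])^2 +
    (x[, 3] - centers[1, 3])^2
  if (nrow(centers) > 1L) {
    for (c in 2:nrow(centers)) {
      d <- (x[, 1] - centers[c, 1])^2 + (x[, 2] - centers[c, 2])^2 +
        (x[, 3] - centers[c, 3])^2
      upd <- d < bestd
      best[upd] <- c
      bestd[upd] <- d[upd]
    }
  }
  best
}

#' Reduce an image to k representative colors
#'
#' k-means (Lloyd iterations) on the Cartesian embedding of HSV so that the
#' clustering metric is plain Euclidean distance.  Seeding is
#' farthest-point from a seeded RNG with `restarts` independent restarts;
#' the solution with the lowest within-cluster sum of squares is kept.
#' Mapping every pixel to its centroid color yields the reduced-palette
#' ("ten-color" at the default `k = 10`) image, see [recolor_image()].
#'
#' @param image HSV raster (`H x W x 3`).
#' @param k number of color clusters (default 10).
#' @param seed RNG seed controlling initialization (and subsampling).
#' @param restarts independent initializations (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param max_pixels above this count pixels are subsampled for fitting and
#'   all pixels then assigned to the nearest centroid; default 1e6 (no
#'   subsampling for ordinary tiles).
#' @return an object of class `clustered_image`: `labels` (`H x W` integer
#'   raster of 0-based cluster ids), `centroids_hsv` and `centroids_cart`
#'   (`k x 3`), `k`, `points` (the `n x 3` Cartesian pixel matrix), and the
#'   within-cluster sum of squares `tot_withinss`.
#' @export
reduce_colors <- function(image, k = 10L, seed = 1L, restarts = 10L,
                          max_iter = 300L, max_pixels = 1e6) {
  d <- raster_dim(image)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  x <- channel_matrix(hsv_to_cartesian(image))
  n <- nrow(x)
  n_distinct <- length(unique(x[, 1] + sqrt(2) * x[, 2] + sqrt(3) * x[, 3]))
  if (k > n_distinct)
    stop("k (", k, ") exceeds the number of distinct pixel colors (",
         n_distinct, ")", call. = FALSE)
  set.seed(seed)
  subsampled <- n > max_pixels
  xfit <- if (subsampled) {
    message("reduce_colors: subsampling ", format(max_pixels, scientific = FALSE),
            " of ", n, " pixels for fitting")
    x[sample.int(n, max_pixels), , drop = FALSE]
  } else x
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- farthest_point_centers(xfit, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(xfit, centers = init,
                                     iter.max = max_iter,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop("k-means failed for every restart", call. = FALSE)
  lab <- if (subsampled) nearest_center(x, best$centers) else best$cluster
  centers <- unname(best$centers)
  structure(list(
    labels = matrix(as.integer(lab) - 1L, d[1], d[2]),
    centroids_cart = centers,
    centroids_hsv = cartesian_to_hsv(centers),
    k = as.integer(k),
    points = x,
    tot_withinss = best$tot.withinss
  ), class = "clustered_image")
}

#' @export
print.clustered_image <- function(x, ...) {
  cat("clustered_image: ", nrow(x$labels), "x", ncol(x$labels),
      " pixels, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Recolor a clustered image with its centroid colors
#'
#' @param clustered a [reduce_colors()] result.
#' @return HSV raster in which every pixel carries its cluster centroid
#'   color; at most `k` distinct colors.
#' @export
recolor_image <- function(clustered) {
  stopifnot(inherits(clustered, "clustered_image"))
  hsv <- clustered$centroids_hsv[as.vector(clustered$labels) + 1L, ]
  channel_array(hsv, c(dim(clustered$labels), 3L))
}

#' Mean intra-/inter-cluster variance ratio
#'
#' Diagnostic for choosing the palette size.  For each cluster the
#' intra-cluster variance is the mean squared Cartesian distance of its
#' members to the centroid and the inter-cluster variance the mean squared
#' distance from that centroid to the other `k - 1` centroids; the mean of
#' the per-cluster ratios is returned.  The ratio declines and plateaus as
#' k grows, which motivates the default palette of 10 colors.
#'
#' @param clustered a [reduce_colors()] result with `k >= 2`.
#' @return nonnegative scalar; empty clusters are excluded with a warning.
#' @export
cluster_variance_ratio <- function(clustered) {
  stopifnot(inherits(clustered, "clustered_image"))
  k <- clustered$k
  if (k < 2L) stop("variance ratio requires k >= 2", call. = FALSE)
  lab <- as.vector(clustered$labels) + 1L
  x <- clustered$points
  cent <- clustered$centroids_cart
  ratios <- numeric(0)
  for (c in seq_len(k)) {
    mem <- lab == c
    if (!any(mem)) {
      warning("cluster ", c - 1L, " is empty and excluded from the ratio")
      next
    }
    dx <- x[mem, , drop = FALSE]
    intra <- mean((dx[, 1] - cent[c, 1])^2 + (dx[, 2] - cent[c, 2])^2 +
                    (dx[, 3] - cent[c, 3])^2)
    oth <- cent[-c, , drop = FALSE]
    inter <- mean((oth[, 1] - cent[c, 1])^2 + (oth[, 2] - cent[c, 2])^2 +
                    (oth[, 3] - cent[c, 3])^2)
    ratios <- c(ratios, intra / inter)
  }
  mean(ratios)
}

#' Variance-ratio curve over cluster counts
#'
#' @param image HSV raster.
#' @param ks integer vector of cluster counts, all `>= 2`.
#' @param seeds RNG seeds; the ratio at each k is averaged over seeds.
#' @param ... passed on to [reduce_colors()].
#' @return data frame with columns `k` and `ratio`, ordered by `k`;
#'   the seeds used are attached as an attribute.
#' @export
variance_curve <- function(image, ks, seeds = 1L, ...) {
  if (any(ks < 2L)) stop("all ks must be >= 2", call. = FALSE)
  ks <- sort(unique(as.integer(ks)))
  ratio <- vapply(ks, function(k) {
    mean(vapply(seeds, function(s)
      cluster_variance_ratio(reduce_colors(image, k = k, seed = s, ...)),
      numeric(1)))
  }, numeric(1))
  structure(data.frame(k = ks, ratio = ratio), seeds = seeds)
}
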