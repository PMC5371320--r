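# shared fixtures, all generated in code

# a small synthetic tile with ground truth
tile_fixture <- function(size = 96, seed = 1, sigma = 0.02,
                         shift = c(0, 0, 0)) {
  lay <- generate_layout(c(size, size), seed = seed)
  render_tile(lay, stain_profile(shift = shift, sigma = sigma),
              seed = seed + 1000L)
}

# build a clustered_image by hand (for assignment tests)
manual_clustered <- function(labels0, points, centroids_cart = NULL) {
  k <- max(labels0) + 1L
  if (is.null(centroids_cart))
    centroids_cart <- t(vapply(0:(k - 1L), function(c)
      colMeans(points[as.vector(labels0) == c, , drop = FALSE]),
      numeric(3)))
  structure(list(labels = labels0, points = points,
                 centroids_cart = centroids_cart,
                 centroids_hsv = cartesian_to_hsv(centroids_cart),
                 k = k),
            class = "clustered_image")
}

# an HSV image from an n x 3 matrix of pixel rows, laid out as one column
hsv_image <- function(rows) array(rows, dim = c(nrow(rows), 1L, 3L))

# full (non-cascade) assignment of every cluster by modal truth class
full_assignment <- function(k, classes) {
  m <- classes
  names(m) <- as.character(0:(k - 1L))
  color_assignment(m, k)
}

# smallest circular difference between two hue rasters
hue_dist <- function(a, b) abs(((a - b + 0.5) %% 1) - 0.5)

# independent brute-force MI oracle: dense joint histogram, triple loop
mi_oracle <- function(x, y, bins) {
  bx <- pmin(floor(pmax(x, 0) * bins), bins - 1) + 1
  by <- pmin(floor(pmax(y, 0) * bins), bins - 1) + 1
  joint <- matrix(0, bins, bins)
  for (i in seq_along(bx)) joint[bx[i], by[i]] <- joint[bx[i], by[i]] + 1
  joint <- joint / length(bx)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in 1:bins) for (j in 1:bins) {
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  }
  mi
}
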