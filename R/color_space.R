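#' Convert an RGB raster to HSV
#'
#' Standard hexcone conversion with hue scaled to `[0, 1)`.  Achromatic
#' pixels receive hue 0.
#'
#' @param image numeric `H x W x 3` array, channels R, G, B in `[0, 1]`.
#' @return numeric `H x W x 3` array, channels hue, saturation, value.
#' @export
#' @examples
#' px <- array(c(0, 0, 1), dim = c(1, 1, 3))  # pure blue
#' rgb_to_hsv(px)[1, 1, ]                     # h = 2/3, s = 1, v = 1
rgb_to_hsv <- function(image) {
  d <- raster_dim(image)
  m <- channel_matrix(image)
  if (any(!is.finite(m)))
    stop("RGB image contains non-finite values", call. = FALSE)
  if (any(m < 0) || any(m > 1))
    stop("RGB channels must lie in [0, 1]", call. = FALSE)
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  hsv[, 1] <- hsv[, 1] %% 1
  channel_array(hsv, d)
}

#' Convert an HSV raster to RGB
#'
#' Exact hexcone inverse, kept in floating point: no 8-bit quantization
#' occurs until an image file is written.
#'
#' @param image numeric `H x W x 3` array, channels hue (circular),
#'   saturation, value, all in `[0, 1]`.
#' @return numeric `H x W x 3` RGB array in `[0, 1]`.
#' @export
hsv_to_rgb <- function(image) {
  d <- raster_dim(image)
  m <- channel_matrix(image)
  h <- (m[, 1] %% 1) * 6
  s <- clamp01(m[, 2])
  v <- clamp01(m[, 3])
  i <- as.integer(floor(h)) %% 6L
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  sel <- i == 0L; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- i == 1L; r[sel] <- q[sel]; b[sel] <- p[sel]
  sel <- i == 2L; r[sel] <- p[sel]; b[sel] <- t[sel]
  sel <- i == 3L; r[sel] <- p[sel]; g[sel] <- q[sel]
  sel <- i == 4L; r[sel] <- t[sel]; g[sel] <- p[sel]
  sel <- i == 5L; g[sel] <- p[sel]; b[sel] <- q[sel]
  channel_array(cbind(r, g, b, deparse.level = 0), d)
}

#' Embed HSV colors in Cartesian coordinates
#'
#' Maps `(h, s, v)` to `(s cos 2πh, s sin 2πh, v)`.  HSV is cylindrical, so
#' Euclidean distance is only meaningful after this embedding; it is the
#' metric used for clustering and classification throughout the package.
#'
#' @param x HSV raster (`H x W x 3` array) or an `n x 3` matrix of HSV rows.
#' @return array or matrix of the same shape with channels x, y, z.
#' @export
hsv_to_cartesian <- function(x) {
  if (is.matrix(x)) {
    m <- x
    out_shape <- NULL
  } else {
    out_shape <- raster_dim(x)
    m <- channel_matrix(x)
  }
  a <- 2 * pi * (m[, 1] %% 1)
  s <- clamp01(m[, 2])
  out <- cbind(s * cos(a), s * sin(a), clamp01(m[, 3]), deparse.level = 0)
  if (is.null(out_shape)) out else channel_array(out, out_shape)
}

#' Invert the Cartesian embedding back to HSV
#'
#' `s = sqrt(x^2 + y^2)`, `h = atan2(y, x) / 2π (mod 1)`, `v = z`.
#' Achromatic points (`s = 0`) get hue 0 by convention so the inverse is
#' deterministic.
#'
#' @param x Cartesian raster or `n x 3` matrix.
#' @param tol tolerance on `x^2 + y^2 <= 1`; radii beyond `1 + tol` raise an
#'   error, radii within it are clamped to 1.
#' @return HSV values in the same shape as the input.
#' @export
cartesian_to_hsv <- function(x, tol = 1e-6) {
  if (is.matrix(x)) {
    m <- x
    out_shape <- NULL
  } else {
    out_shape <- raster_dim(x)
    m <- channel_matrix(x)
  }
  s <- sqrt(m[, 1]^2 + m[, 2]^2)
  if (any(s > 1 + tol))
    stop("point outside the HSV cylinder: x^2 + y^2 > 1", call. = FALSE)
  s <- pmin(s, 1)
  h <- numeric(length(s))
  chrom <- s > 0
  h[chrom] <- (atan2(m[chrom, 2], m[chrom, 1]) / (2 * pi)) %% 1
  out <- cbind(h, s, clamp01(m[, 3]), deparse.level = 0)
  if (is.null(out_shape)) out else channel_array(out, out_shape)
}
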