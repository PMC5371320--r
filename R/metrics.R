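# integer bin codes for channel values in [0, 1]; the top edge folds into
# the last bin
bin_codes <- function(x, bins) {
  pmin.int(floor(clamp01(x) * bins), bins - 1L) + 1L
}

# codes for one channel (matrix) or a joint pair of channels (H x W x 2)
raster_codes <- function(x, bins) {
  if (is.matrix(x)) return(list(codes = bin_codes(as.vector(x), bins),
                                nstates = bins))
  d <- dim(x)
  if (length(d) == 3L && d[3] == 2L) {
    c1 <- bin_codes(as.vector(x[, , 1]), bins)
    c2 <- bin_codes(as.vector(x[, , 2]), bins)
    return(list(codes = (c1 - 1L) * bins + c2, nstates = bins * bins))
  }
  stop("expected a single-channel matrix or an H x W x 2 channel pair",
       call. = FALSE)
}

# plug-in MI in bits from paired integer codes; joint counted sparsely
mi_from_codes <- function(cx, cy, nx, ny) {
  n <- length(cx)
  px <- tabulate(cx, nbins = nx) / n
  py <- tabulate(cy, nbins = ny) / n
  key <- (as.numeric(cx) - 1) * ny + as.numeric(cy)
  r <- rle(sort(key))
  pj <- r$lengths / n
  i <- (r$values - 1) %/% ny + 1
  j <- (r$values - 1) %% ny + 1
  sum(pj * log2(pj / (px[i] * py[j])))
}

#' Histogram mutual information between two images
#'
#' Plug-in estimator over the joint distribution of paired pixel values.
#' Inputs are either single channels (`H x W` matrices, e.g. the value
#' channel) or two-channel planes (`H x W x 2` arrays, e.g. hue-saturation,
#' binned jointly on a `bins x bins` grid).
#'
#' @param x,y same-shape channel rasters.
#' @param bins histogram bins per channel (default 64).
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 64L) {
  if (!identical(dim(x), dim(y)))
    stop("x and y must have the same shape", call. = FALSE)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  a <- raster_codes(x, bins)
  b <- raster_codes(y, bins)
  mi_from_codes(a$codes, b$codes, a$nstates, b$nstates)
}

#' Normalized mutual information between two HSV images
#'
#' `MI(X, Y) / MI(X, X)` per channel group, where `MI(X, X)` is the entropy
#' of X's binned distribution.  Measured separately on the value channel
#' and the hue-saturation plane (2-D joint histogram).  `nmi(x, x)` is 1
#' for any nonconstant image.
#'
#' The hue-saturation plane is binned more coarsely per channel
#' (`bins_joint`, default 16, i.e. 256 joint states): the plug-in MI
#' estimator's upward small-sample bias scales with the number of occupied
#' histogram states over the pixel count, and a 2-D plane at the 1-D bin
#' width would leave tile-sized images far outside the estimator's
#' consistent regime.
#'
#' @param x reference (unnormalized) HSV raster.
#' @param y comparison HSV raster, same shape.
#' @param bins histogram bins for single channels (default 64).
#' @param bins_joint bins per channel for the 2-D hue-saturation joint
#'   (default 16).
#' @return named numeric vector `c(value = ..., huesat = ...)`.
#' @export
nmi <- function(x, y, bins = 64L, bins_joint = 16L) {
  dx <- raster_dim(x)
  if (!identical(dx, raster_dim(y)))
    stop("x and y must have the same shape", call. = FALSE)
  groups <- list(
    value  = list(get = function(img) img[, , 3, drop = TRUE], b = bins),
    huesat = list(get = function(img) img[, , 1:2, drop = FALSE],
                  b = bins_joint)
  )
  vapply(groups, function(g) {
    self <- mutual_information(g$get(x), g$get(x), g$b)
    if (self <= 0)
      stop("NMI undefined: reference channel is constant", call. = FALSE)
    mutual_information(g$get(x), g$get(y), g$b) / self
  }, numeric(1))
}

#' Add isotropic Gaussian noise in HSV space
#'
#' i.i.d. `N(0, sigma^2)` noise added to each HSV channel; hue is wrapped
#' modulo 1, saturation and value clipped to `[0, 1]` (same conventions as
#' normalization).  `sigma = 0` is the identity.
#'
#' @param image HSV raster.
#' @param sigma noise standard deviation in HSV units.
#' @param seed RNG seed; a fixed seed reproduces the same noise field.
#' @return noisy HSV raster.
#' @export
add_hsv_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  d <- raster_dim(image)
  if (sigma == 0) return(image)
  set.seed(seed)
  m <- channel_matrix(image) + matrix(rnorm(prod(d), 0, sigma), ncol = 3L)
  m[, 1] <- wrap01(m[, 1])
  m[, 2] <- clamp01(m[, 2])
  m[, 3] <- clamp01(m[, 3])
  channel_array(m, d)
}

#' NMI as a function of added noise
#'
#' Computes `nmi(image, image + noise)` over a grid of noise levels — the
#' calibration that translates NMI values into visually interpretable
#' amounts of corruption.  The curve is nonincreasing in sigma (in
#' expectation).
#'
#' @param image HSV raster.
#' @param sigmas noise standard deviations; the default grid spans 0.001
#'   to 0.5.
#' @param seed RNG seed (one child seed per sigma).
#' @param bins,bins_joint histogram bins, see [nmi()].
#' @return data frame with columns `sigma`, `nmi_value`, `nmi_huesat`.
#' @export
noise_nmi_curve <- function(image,
                            sigmas = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5),
                            seed = 1L, bins = 64L, bins_joint = 16L) {
  if (any(sigmas < 0)) stop("sigmas must be >= 0", call. = FALSE)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, length(sigmas))
  rows <- lapply(seq_along(sigmas), function(i) {
    v <- nmi(image, add_hsv_noise(image, sigmas[i], seed = child[i]), bins,
             bins_joint)
    data.frame(sigma = sigmas[i], nmi_value = v[["value"]],
               nmi_huesat = v[["huesat"]])
  })
  do.call(rbind, rows)
}

# shared worker: per-(class, channel) dispersion table
variability_table <- function(values_fn) {
  cls <- tissue_classes()
  rows <- list()
  for (c in 1:4) {
    for (ch in c("h", "s", "v")) {
      if (c == 1L && ch == "h") next  # hue is meaningless for white
      v <- values_fn(c, ch)
      if (is.null(v)) next
      rows[[length(rows) + 1L]] <-
        data.frame(class = cls[c], channel = ch, sd = v)
    }
  }
  do.call(rbind, rows)
}

#' Inter-image variability of structure means
#'
#' Standard deviation, over a cohort of images, of the per-image mean color
#' of each tissue structure — the quantity that color normalization is
#' meant to shrink.  Population convention (divide by n); circular sd for
#' hue; the white-hue entry is omitted because hue carries no meaning for a
#' near-achromatic structure.
#'
#' @param cohort list of pairs, each a list with `image` (HSV raster) and
#'   `classified`; at least 2.
#' @return data frame with columns `class`, `channel`, `sd`.  Classes
#'   absent from every image are omitted with a warning.
#' @export
inter_image_variability <- function(cohort) {
  if (length(cohort) < 2L)
    stop("need at least 2 images", call. = FALSE)
  means <- lapply(cohort, function(p)
    suppressWarnings(structure_means(p$image, p$classified)))
  chi <- c(h = 1L, s = 2L, v = 3L)
  out <- variability_table(function(c, ch) {
    v <- vapply(means, function(m) m[c, chi[[ch]]], numeric(1))
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning("class ", tissue_classes()[c],
              " absent from every image; omitted")
      return(NULL)
    }
    if (ch == "h") circ_sd01(v) else pop_sd(v)
  })
  out
}

#' Intra-image variability of pixel colors per structure
#'
#' Per-structure, per-channel standard deviation of pixel values within one
#' image (population convention, circular for hue).  Deviation-preserving
#' normalization leaves these unchanged wherever no pixel clips.
#'
#' @param image HSV raster.
#' @param classified aligned classification.
#' @return data frame with columns `class`, `channel`, `sd`.
#' @export
intra_image_variability <- function(image, classified) {
  m <- channel_matrix(image)
  cls <- as.vector(as_class_map(classified))
  chi <- c(h = 1L, s = 2L, v = 3L)
  variability_table(function(c, ch) {
    sel <- cls == c
    if (!any(sel)) return(NULL)
    v <- m[sel, chi[[ch]]]
    if (ch == "h") circ_sd01(v) else pop_sd(v)
  })
}

#' Pre/post variability report with reduction factors
#'
#' Joins two [inter_image_variability()] tables and reports, per
#' (class, channel), the factor by which normalization reduced the
#' inter-image standard deviation.
#'
#' @param pre,post variability tables for the unnormalized and normalized
#'   cohort.
#' @return data frame with columns `class`, `channel`, `pre_sd`, `post_sd`,
#'   `reduction` (`pre_sd / post_sd`, `NA` when `post_sd` is 0).
#' @export
variability_report <- function(pre, post) {
  rep <- merge(pre, post, by = c("class", "channel"),
               suffixes = c("_pre", "_post"))
  names(rep)[names(rep) == "sd_pre"] <- "pre_sd"
  names(rep)[names(rep) == "sd_post"] <- "post_sd"
  rep$reduction <- ifelse(rep$post_sd > 0, rep$pre_sd / rep$post_sd, NA_real_)
  rep[order(match(rep$class, tissue_classes()), rep$channel), ]
}
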