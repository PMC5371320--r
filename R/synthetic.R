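#' Default base colors for synthetic H&E tiles
#'
#' Approximate H&E appearance: nuclei blue-purple (hematoxylin), cytoplasm
#' pink and stroma a lighter pink (eosin), white/lumen near-achromatic and
#' bright.  Chosen so the four classes are well separated (pairwise
#' Cartesian distance > 0.2) at the default noise level.
#'
#' @return 4 x 3 HSV matrix, rows `white, stroma, nuclei, cytoplasm`.
#' @export
default_base_colors <- function() {
  m <- rbind(white     = c(0.00, 0.02, 0.97),
             stroma    = c(0.93, 0.25, 0.85),
             nuclei    = c(0.70, 0.55, 0.35),
             cytoplasm = c(0.92, 0.45, 0.72))
  colnames(m) <- c("h", "s", "v")
  m
}

#' Stain profile for one synthetic tile
#'
#' @param base 4 x 3 HSV base color matrix (rows named by class).
#' @param shift length-3 global HSV shift applied to every pixel — the
#'   per-image stain drift the normalizer is meant to remove.
#' @param sigma per-pixel Gaussian color noise sd in HSV units
#'   (default 0.02).
#' @return object of class `stain_profile`.
#' @export
stain_profile <- function(base = default_base_colors(),
                          shift = c(0, 0, 0), sigma = 0.02) {
  stopifnot(length(shift) == 3L, sigma >= 0)
  if (base["white", "s"] > 0.05)
    stop("white base saturation must be <= 0.05", call. = FALSE)
  structure(list(base = base, shift = as.numeric(shift), sigma = sigma),
            class = "stain_profile")
}

default_geometry <- function() {
  list(stroma_frac = 0.30, lumen_frac = 0.12, nuclei_frac = 0.15,
       nucleus_radius = c(3, 7), lumen_radius = c(10, 24),
       band_period = c(40, 80))
}

# paint an ellipse / perturbed blob inside its bounding box; returns the
# updated label matrix and the number of pixels painted
paint_region <- function(labels, cy, cx, rmax, value, inside, skip_white) {
  h <- nrow(labels); w <- ncol(labels)
  rows <- max(1L, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  dy <- rows - cy
  dx <- cols - cx
  mask <- inside(matrix(dy, length(rows), length(cols)),
                 matrix(dx, length(rows), length(cols), byrow = TRUE))
  patch <- labels[rows, cols, drop = FALSE]
  if (skip_white) mask <- mask & patch != 1L
  painted <- sum(mask & patch != value)
  patch[mask] <- value
  labels[rows, cols] <- patch
  list(labels = labels, painted = painted)
}

#' Generate a ground-truth tissue layout
#'
#' Deterministic (given the seed) four-class label raster emulating an H&E
#' tile: oriented stroma bands on a cytoplasm background, smooth lumen
#' blobs, and elliptical nuclei scattered through the tissue.  Class area
#' fractions are driven toward the requested `*_frac` targets.
#'
#' @param size image size, `c(H, W)` or a scalar; at least 64.
#' @param geometry list overriding [default_geometry()] entries:
#'   `stroma_frac`, `lumen_frac`, `nuclei_frac` (all `> 0`, summing below
#'   0.85), `nucleus_radius`, `lumen_radius`, `band_period` (ranges in
#'   pixels).
#' @param seed RNG seed.
#' @return object of class `tissue_layout` with `labels` (`H x W` integers,
#'   1 = white, 2 = stroma, 3 = nuclei, 4 = cytoplasm) and the geometry
#'   used.
#' @export
generate_layout <- function(size = c(256L, 256L), geometry = list(),
                            seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 64L)) stop("size must be at least 64 x 64", call. = FALSE)
  g <- utils::modifyList(default_geometry(), geometry)
  fr <- c(g$stroma_frac, g$lumen_frac, g$nuclei_frac)
  if (any(fr <= 0))
    stop("all four classes are required: stroma_frac, lumen_frac and ",
         "nuclei_frac must be > 0", call. = FALSE)
  if (sum(fr) >= 0.85)
    stop("infeasible geometry: requested fractions leave no cytoplasm",
         call. = FALSE)
  h <- as.integer(size[1]); w <- as.integer(size[2])
  set.seed(seed)
  labels <- matrix(4L, h, w)  # cytoplasm background

  # oriented stroma bands; duty cycle compensates for later overpainting
  theta <- runif(1, 0, pi)
  period <- runif(1, g$band_period[1], g$band_period[2])
  phase <- runif(1, 0, period)
  duty <- min(0.95, g$stroma_frac / ((1 - g$lumen_frac) * (1 - g$nuclei_frac)))
  proj <- outer(seq_len(h) * sin(theta), seq_len(w) * cos(theta), "+")
  labels[((proj + phase) %% period) < duty * period] <- 2L

  # lumen: smooth perturbed blobs painted until the area target is met
  target <- round(g$lumen_frac * h * w)
  painted <- 0L
  for (i in seq_len(300L)) {
    if (painted >= target) break
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    r0 <- runif(1, g$lumen_radius[1], g$lumen_radius[2])
    ps <- runif(2, 0, 2 * pi)
    res <- paint_region(labels, cy, cx, 1.4 * r0, 1L, function(dy, dx) {
      ang <- atan2(dy, dx)
      rad <- sqrt(dy^2 + dx^2)
      rad <= r0 * (1 + 0.25 * sin(3 * ang + ps[1]) +
                     0.15 * sin(5 * ang + ps[2]))
    }, skip_white = FALSE)
    labels <- res$labels
    painted <- painted + res$painted
  }

  # nuclei: ellipses with centers in tissue, never painted over lumen
  target <- round(g$nuclei_frac * h * w)
  painted <- 0L
  mean_area <- pi * mean(g$nucleus_radius)^2
  for (i in seq_len(max(50L, 20L * ceiling(target / mean_area)))) {
    if (painted >= target) break
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    if (labels[round(cy), round(cx)] == 1L) next
    a <- runif(1, g$nucleus_radius[1], g$nucleus_radius[2])
    b <- runif(1, g$nucleus_radius[1], g$nucleus_radius[2])
    th <- runif(1, 0, pi)
    res <- paint_region(labels, cy, cx, max(a, b), 3L, function(dy, dx) {
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      u^2 + v^2 <= 1
    }, skip_white = TRUE)
    labels <- res$labels
    painted <- painted + res$painted
  }

  if (!all(1:4 %in% labels))
    stop("layout generation failed to place all four classes; ",
         "adjust geometry", call. = FALSE)
  structure(list(labels = labels, geometry = g, size = c(h, w)),
            class = "tissue_layout")
}

#' Render a synthetic H&E tile from a layout and stain profile
#'
#' Pixel color = class base color + global stain shift + i.i.d. Gaussian
#' noise, per HSV channel; hue wrapped, saturation/value clipped; converted
#' to RGB.
#'
#' @param layout a [generate_layout()] result.
#' @param profile a [stain_profile()].
#' @param seed RNG seed for the pixel noise.
#' @return list with `image` (`H x W x 3` RGB raster), `labels`
#'   (ground-truth class raster), `profile`.
#' @export
render_tile <- function(layout, profile = stain_profile(), seed = 1L) {
  stopifnot(inherits(layout, "tissue_layout"),
            inherits(profile, "stain_profile"))
  set.seed(seed)
  cls <- as.vector(layout$labels)
  n <- length(cls)
  m <- profile$base[cls, , drop = FALSE] +
    matrix(profile$shift, n, 3L, byrow = TRUE)
  if (profile$sigma > 0)
    m <- m + matrix(rnorm(3L * n, 0, profile$sigma), ncol = 3L)
  m[, 1] <- wrap01(m[, 1])
  m[, 2] <- clamp01(m[, 2])
  m[, 3] <- clamp01(m[, 3])
  hsv <- channel_array(m, c(layout$size, 3L))
  list(image = hsv_to_rgb(hsv), labels = layout$labels, profile = profile)
}

#' Generate a cohort of synthetic tiles with stain drift
#'
#' Each image gets its own tissue layout and an i.i.d. Gaussian global HSV
#' shift of sd `sigma_shift` per channel — the population-level stain
#' variability ("vastly different color properties") that normalization
#' should remove.  All randomness derives from the master seed, so cohorts
#' are bit-reproducible.
#'
#' @param n number of images (default 20).
#' @param size tile size (default 256 x 256).
#' @param base_colors population base colors (default
#'   [default_base_colors()]).
#' @param sigma_shift per-channel sd of the per-image global shift
#'   (default 0.05).
#' @param sigma per-pixel noise sd (default 0.02).
#' @param geometry layout geometry overrides, see [generate_layout()].
#' @param seed master RNG seed.
#' @return list of `n` tiles, each a [render_tile()] result.
#' @export
generate_cohort <- function(n = 20L, size = c(256L, 256L),
                            base_colors = default_base_colors(),
                            sigma_shift = 0.05, sigma = 0.02,
                            geometry = list(), seed = 1L) {
  stopifnot(n >= 1L, sigma_shift >= 0, sigma >= 0)
  set.seed(seed)
  shifts <- matrix(rnorm(3L * n, 0, sigma_shift), ncol = 3L)
  layout_seeds <- sample.int(.Machine$integer.max, n)
  render_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    lay <- generate_layout(size, geometry, seed = layout_seeds[i])
    prof <- stain_profile(base_colors, shifts[i, ], sigma)
    render_tile(lay, prof, seed = render_seeds[i])
  })
}
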