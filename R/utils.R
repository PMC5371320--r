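# internal numeric helpers; hue lives on the unit circle throughout

clamp01 <- function(x) pmin(pmax(x, 0), 1)

wrap01 <- function(x) x %% 1

# shortest signed difference a - b on the hue circle, result in [-0.5, 0.5)
circ_diff01 <- function(a, b) ((a - b + 0.5) %% 1) - 0.5

# circular mean of hues in [0, 1); resultant-vector definition
circ_mean01 <- function(h) {
  (atan2(mean(sin(2 * pi * h)), mean(cos(2 * pi * h))) / (2 * pi)) %% 1
}

# circular standard deviation, converted back to hue units so that for
# small dispersion it agrees with the linear (population) sd
circ_sd01 <- function(h) {
  r <- sqrt(mean(sin(2 * pi * h))^2 + mean(cos(2 * pi * h))^2)
  r <- min(r, 1)
  if (r <= .Machine$double.eps) return(NA_real_)
  sqrt(-2 * log(r)) / (2 * pi)
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# coerce an H x W x 3 raster to an n x 3 channel matrix and back
channel_matrix <- function(image) matrix(image, ncol = 3L)

channel_array <- function(m, dim3) array(m, dim = dim3)

raster_dim <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 image array", call. = FALSE)
  d
}
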