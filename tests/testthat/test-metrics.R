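test_that("mutual information matches hand-computable cases", {
  x <- matrix(0.3, 4, 4)
  y <- matrix(runif(16), 4, 4)
  expect_equal(mutual_information(x, y, bins = 8), 0)
  # fair bit: two equiprobable values, y = x
  x2 <- matrix(rep(c(0.1, 0.9), 8), 4, 4)
  expect_equal(mutual_information(x2, x2, bins = 4), 1)
  expect_error(mutual_information(x, matrix(0, 2, 2)), "same shape")
  expect_error(mutual_information(x, y, bins = 1), "bins")
})

test_that("the MI estimator equals a brute-force oracle on 4x4 toys", {
  set.seed(99)
  for (rep in 1:5) {
    x <- matrix(runif(16), 4, 4)
    y <- (x + matrix(runif(16, 0, 0.5), 4, 4)) %% 1
    for (bins in c(2, 5, 16))
      expect_equal(mutual_information(x, y, bins),
                   mi_oracle(as.vector(x), as.vector(y), bins),
                   tolerance = 1e-12)
  }
})

test_that("MI is bounded by the marginal entropies", {
  set.seed(17)
  entropy <- function(x, bins) mutual_information(x, x, bins)
  for (rep in 1:5) {
    x <- matrix(runif(400), 20, 20)
    y <- matrix(runif(400), 20, 20)
    mi <- mutual_information(x, y, 16)
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy(x, 16), entropy(y, 16)) + 1e-12)
  }
})

test_that("NMI of an image with itself is exactly 1", {
  tile <- tile_fixture(64, seed = 23)
  hsv <- rgb_to_hsv(tile$image)
  expect_identical(unname(nmi(hsv, hsv)), c(1, 1))
  expect_error(nmi(array(0.5, c(4, 4, 3)), array(0.5, c(4, 4, 3))),
               "constant")
})

test_that("NMI of independent images is at the permutation baseline", {
  t1 <- tile_fixture(96, seed = 24)
  t2 <- tile_fixture(96, seed = 77, shift = c(0.05, 0, 0))
  x <- rgb_to_hsv(t1$image)
  y <- rgb_to_hsv(t2$image)
  set.seed(5)
  perm <- array(matrix(x, ncol = 3)[sample(96 * 96), ], dim = dim(x))
  v_ind <- nmi(x, y)
  v_perm <- nmi(x, perm)
  # chance-level agreement: close to the permutation bias, far below 1
  expect_lt(v_ind[["value"]], v_perm[["value"]] + 0.05)
  expect_lt(v_ind[["huesat"]], v_perm[["huesat"]] + 0.1)
  expect_lt(v_ind[["value"]], 0.3)
})

test_that("deviation-preserving normalization beats the flat control in NMI", {
  tile <- tile_fixture(96, seed = 25, shift = c(0.02, -0.02, 0.02))
  p <- process_image(tile$image, truth = tile$labels, seed = 1)
  tg <- default_base_colors()
  v_dev <- nmi(p$hsv, normalize_image(p$hsv, p$classified, tg))
  v_flat <- nmi(p$hsv, normalize_without_deviation(p$hsv, p$classified, tg))
  expect_gt(v_dev[["value"]], v_flat[["value"]])
  expect_gt(v_dev[["huesat"]], v_flat[["huesat"]])
})

test_that("HSV noise has the requested statistics and is reproducible", {
  img <- array(0.5, dim = c(1000, 1000, 3))
  expect_identical(add_hsv_noise(img, 0), img)
  a <- add_hsv_noise(img, 0.05, seed = 3)
  b <- add_hsv_noise(img, 0.05, seed = 3)
  expect_identical(a, b)
  # empirical sd within 2% of sigma at 1e6 samples per channel
  for (ch in 1:3) {
    diff <- a[, , ch] - 0.5
    expect_lt(abs(sd(diff) - 0.05) / 0.05, 0.02)
  }
})

test_that("the noise-NMI curve starts at 1 and never increases", {
  tile <- tile_fixture(64, seed = 26)
  hsv <- rgb_to_hsv(tile$image)
  z <- noise_nmi_curve(hsv, sigmas = 0, seed = 1)
  expect_equal(unlist(z[1, ]), c(sigma = 0, nmi_value = 1, nmi_huesat = 1))
  curve <- noise_nmi_curve(hsv, sigmas = c(0.005, 0.05, 0.5), seed = 1)
  expect_true(all(diff(curve$nmi_value) <= 0))
  expect_true(all(diff(curve$nmi_huesat) <= 0))
})

test_that("inter-image variability follows the population-sd convention", {
  img1 <- hsv_image(rbind(c(0.7, 0.5, 0.4)))
  img2 <- hsv_image(rbind(c(0.7, 0.5, 0.6)))
  cm <- matrix(3L)
  v <- suppressWarnings(inter_image_variability(list(
    list(image = img1, classified = cm),
    list(image = img2, classified = cm))))
  expect_equal(v$sd[v$class == "nuclei" & v$channel == "v"], 0.1,
               tolerance = 1e-12)
  # identical cohort -> all zeros
  v0 <- suppressWarnings(inter_image_variability(list(
    list(image = img1, classified = cm),
    list(image = img1, classified = cm))))
  expect_true(all(v0$sd == 0))
  # white x hue is never reported
  expect_false(any(v$class == "white" & v$channel == "h"))
})

test_that("intra-image variability is zero for flat maps and preserved by Dd", {
  tile <- tile_fixture(96, seed = 27)
  p <- process_image(tile$image, truth = tile$labels, seed = 1)
  tg <- p$means  # own means: no clipping beyond what the input had
  flat <- normalize_without_deviation(p$hsv, p$classified, tg)
  v_flat <- intra_image_variability(flat, p$classified)
  expect_true(all(v_flat$sd < 1e-12))
  v_pre <- intra_image_variability(p$hsv, p$classified)
  v_post <- intra_image_variability(
    normalize_image(p$hsv, p$classified, tg), p$classified)
  expect_equal(v_post$sd, v_pre$sd, tolerance = 0.02)
})

test_that("variability reports compute reduction factors", {
  pre <- data.frame(class = "nuclei", channel = "v", sd = 0.3)
  post <- data.frame(class = "nuclei", channel = "v", sd = 0.05)
  rep <- variability_report(pre, post)
  expect_equal(rep$reduction, 6)
})
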