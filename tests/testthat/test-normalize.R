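test_that("structure means are arithmetic in s, v and circular in hue", {
  img <- hsv_image(rbind(c(0.95, 0.5, 0.4), c(0.05, 0.7, 0.6)))
  cm <- matrix(3L, 2, 1)  # both nuclei
  m <- suppressWarnings(structure_means(img, cm))
  # wraparound: hues 0.95 and 0.05 average to 0 (mod 1), not 0.5
  expect_lt(hue_dist(m["nuclei", "h"], 0), 1e-12)
  expect_equal(unname(m["nuclei", 2:3]), c(0.6, 0.5), tolerance = 1e-12)
  expect_true(all(is.na(m["stroma", ])))

  uni <- hsv_image(rbind(c(0.3, 0.2, 0.9)))
  expect_equal(unname(suppressWarnings(
    structure_means(uni, matrix(1L)))["white", ]),
    c(0.3, 0.2, 0.9))
})

test_that("structure means recover generator base colors", {
  shift <- c(0.01, -0.02, 0.015)
  tile <- tile_fixture(96, seed = 14, sigma = 0.02, shift = shift)
  m <- structure_means(rgb_to_hsv(tile$image), tile$labels)
  base <- default_base_colors()
  for (c in 2:4) {  # chromatic classes; white clips in saturation
    n <- sum(tile$labels == c)
    tol <- 5 * 0.02 / sqrt(n) + 1 / 255
    expect_lt(hue_dist(m[c, "h"], (base[c, "h"] + shift[1]) %% 1), tol)
    expect_lt(abs(m[c, "s"] - (base[c, "s"] + shift[2])), tol)
    expect_lt(abs(m[c, "v"] - (base[c, "v"] + shift[3])), tol)
  }
})

test_that("derived targets average per-image structure means", {
  tile <- tile_fixture(64, seed = 15)
  hsv <- rgb_to_hsv(tile$image)
  pair <- list(image = hsv, classified = tile$labels)
  expect_equal(derive_targets(list(pair)), structure_means(hsv, tile$labels))

  # two images with symmetric structure means -> midpoint targets
  delta <- c(0.05, 0.1, 0.1)
  mid <- rbind(c(0.1, 0.03, 0.9), c(0.9, 0.3, 0.7),
               c(0.7, 0.5, 0.4), c(0.95, 0.4, 0.6))
  cm4 <- matrix(1:4, 4, 1)
  tg <- derive_targets(list(
    list(image = hsv_image(sweep(mid, 2, delta, "-")), classified = cm4),
    list(image = hsv_image(sweep(mid, 2, delta, "+")), classified = cm4)))
  expect_lt(max(hue_dist(tg[, "h"], mid[, 1])), 1e-9)
  expect_equal(unname(tg[, 2:3]), mid[, 2:3], tolerance = 1e-12)
})

test_that("normalizing onto an image's own means is the identity", {
  tile <- tile_fixture(96, seed = 16)
  p <- process_image(tile$image, truth = tile$labels, seed = 1)
  out <- normalize_image(p$hsv, p$classified, p$means)
  expect_lt(max(hue_dist(out[, , 1], p$hsv[, , 1])), 1e-9)
  # s, v identical wherever nothing clips
  unclipped <- out[, , 2:3] > 0 & out[, , 2:3] < 1
  expect_equal(out[, , 2:3][unclipped], p$hsv[, , 2:3][unclipped],
               tolerance = 1e-9)
})

test_that("deviation about the structure mean is conserved (unclipped)", {
  tile <- tile_fixture(96, seed = 17, shift = c(0.02, 0.03, -0.02))
  p <- process_image(tile$image, truth = tile$labels, seed = 1)
  tg <- default_base_colors()
  out <- normalize_image(p$hsv, p$classified, tg)
  cls <- as.vector(p$classified$class_map)
  m_in <- matrix(p$hsv, ncol = 3)
  m_out <- matrix(out, ncol = 3)
  for (c in 1:4) {
    sel <- cls == c
    dh_in <- hue_dist(m_in[sel, 1], p$means[c, "h"])
    dh_out <- hue_dist(m_out[sel, 1], tg[c, "h"])
    expect_equal(dh_out, dh_in, tolerance = 1e-9)
    for (ch in 2:3) {
      dev_in <- m_in[sel, ch] - p$means[c, ch]
      dev_out <- m_out[sel, ch] - tg[c, ch]
      ok <- m_out[sel, ch] > 0 & m_out[sel, ch] < 1
      expect_equal(dev_out[ok], dev_in[ok], tolerance = 1e-9)
    }
  }
  # each structure's post-normalization mean sits on its target
  post <- structure_means(out, p$classified)
  expect_lt(max(hue_dist(post[2:4, "h"], tg[2:4, "h"])), 0.01)
  expect_lt(max(abs(post[2:4, 2:3] - tg[2:4, 2:3])), 0.01)
})

test_that("normalization is idempotent for fixed targets", {
  tile <- tile_fixture(64, seed = 18)
  p <- process_image(tile$image, truth = tile$labels, seed = 1)
  tg <- default_base_colors()
  once <- normalize_image(p$hsv, p$classified, tg)
  twice <- normalize_image(once, p$classified, tg)
  expect_lt(max(hue_dist(twice[, , 1], once[, , 1])), 1e-6)
  expect_lt(max(abs(twice[, , 2:3] - once[, , 2:3])), 0.02)
})

test_that("the flat (no-deviation) control collapses to class targets", {
  tile <- tile_fixture(64, seed = 19)
  p <- process_image(tile$image, truth = tile$labels, seed = 1)
  tg <- default_base_colors()
  flat <- normalize_without_deviation(p$hsv, p$classified, tg)
  expect_lte(nrow(unique(matrix(flat, ncol = 3))), 4L)

  # uniform single-class image maps to a uniform target field
  uni <- hsv_image(rbind(c(0.7, 0.5, 0.3), c(0.71, 0.5, 0.3)))
  f <- normalize_without_deviation(uni, matrix(3L, 2, 1), tg)
  expect_equal(matrix(f, ncol = 3),
               matrix(rep(unname(tg["nuclei", ]), each = 2), ncol = 3))
})

test_that("a class missing its target passes through with a warning", {
  tile <- tile_fixture(64, seed = 20)
  p <- process_image(tile$image, truth = tile$labels, seed = 1)
  tg <- default_base_colors()
  tg["stroma", ] <- NA_real_
  expect_warning(out <- normalize_image(p$hsv, p$classified, tg), "stroma")
  sel <- as.vector(p$classified$class_map) == 2L
  expect_equal(matrix(out, ncol = 3)[sel, ], matrix(p$hsv, ncol = 3)[sel, ])
})
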