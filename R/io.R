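#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @return `H x W x 3` RGB array in `[0, 1]`; an alpha channel, if present,
#'   is dropped.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] >= 4L)
    img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image to PNG or TIFF (8-bit)
#'
#' Quantization to 8 bits happens here and nowhere else in the pipeline.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param path output path, extension selects the format.
#' @export
write_image <- function(image, path) {
  image <- clamp01(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(image, path),
    tif  = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Write a clustered image as a label raster plus JSON sidecar
#'
#' The label raster is a single-channel 8-bit PNG of cluster ids (0-based);
#' centroids and `k` go to a JSON sidecar.
#'
#' @param clustered a [reduce_colors()] result.
#' @param raster_path output PNG path for the label raster.
#' @param meta_path output JSON path (default: `raster_path` with .json).
#' @export
write_clustered <- function(clustered, raster_path,
                            meta_path = sub("\\.[^.]+$", ".json", raster_path)) {
  stopifnot(inherits(clustered, "clustered_image"))
  if (clustered$k > 256L)
    stop("label raster supports at most 256 clusters", call. = FALSE)
  png::writePNG(clustered$labels / 255, raster_path)
  meta <- list(
    k = clustered$k,
    centroids_hsv = unname(apply(clustered$centroids_hsv, 1, as.numeric,
                                 simplify = FALSE)),
    centroids_cartesian = unname(apply(clustered$centroids_cart, 1,
                                       as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(raster_path)
}

# fixed display palette for class maps: nuclei red, cytoplasm blue,
# stroma green, white/lumen white
class_palette <- function() {
  rbind(white     = c(1, 1, 1),
        stroma    = c(0, 0.6, 0),
        nuclei    = c(0.8, 0, 0),
        cytoplasm = c(0, 0, 0.8))
}

#' Write a classification result to disk
#'
#' The class map is written as an RGB PNG under the fixed palette (nuclei
#' red, cytoplasm blue, stroma green, white/lumen white); the four-channel
#' signed-distance certainty stack as a 32-bit float TIFF.  TIFF samples
#' must lie in `[0, 1]`, so the signed distances `d` are stored affinely as
#' `(d + r) / (2 r)` with the half-range `r = max(abs(d))` recorded in a
#' JSON sidecar; [read_certainty()] inverts the encoding.
#'
#' @param classified a [classify_image()] result.
#' @param map_path PNG path for the class map.
#' @param certainty_path optional TIFF path for the certainty stack.
#' @export
write_classified <- function(classified, map_path, certainty_path = NULL) {
  stopifnot(inherits(classified, "classified_image"))
  pal <- class_palette()
  cm <- classified$class_map
  img <- array(pal[as.vector(cm), ], dim = c(dim(cm), 3L))
  png::writePNG(img, map_path)
  if (!is.null(certainty_path)) {
    r <- max(abs(classified$certainty), 1e-12)
    tiff::writeTIFF((classified$certainty + r) / (2 * r), certainty_path,
                    bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(half_range = r),
                         paste0(certainty_path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(map_path)
}

#' Read back a signed-distance certainty stack
#'
#' @param certainty_path TIFF path written by [write_classified()]; the
#'   accompanying `.json` sidecar must sit next to it.
#' @return `H x W x 4` array of signed distances.
#' @export
read_certainty <- function(certainty_path) {
  meta <- jsonlite::read_json(paste0(certainty_path, ".json"),
                              simplifyVector = TRUE)
  enc <- suppressWarnings(tiff::readTIFF(certainty_path))
  enc * (2 * meta$half_range) - meta$half_range
}

#' Read / write target colors as JSON
#'
#' Schema: `{"white": [h,s,v], "stroma": [h,s,v], "nuclei": [h,s,v],
#' "cytoplasm": [h,s,v]}`.
#'
#' @param path JSON file path.
#' @return `load_targets()`: a 4 x 3 matrix (rows in tissue-class order,
#'   columns h, s, v).
#' @export
load_targets <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- tissue_classes()
  missing <- setdiff(cls, names(j))
  if (length(missing))
    stop("target file missing classes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  t <- do.call(rbind, j[cls])
  colnames(t) <- c("h", "s", "v")
  validate_targets(t)
  t
}

#' @param targets 4 x 3 matrix of HSV target colors (rows named by class).
#' @rdname load_targets
#' @export
write_targets <- function(targets, path) {
  validate_targets(targets)
  j <- lapply(seq_len(nrow(targets)), function(i) as.numeric(targets[i, ]))
  names(j) <- rownames(targets)
  jsonlite::write_json(j, path, digits = NA)
  invisible(path)
}
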