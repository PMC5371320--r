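#' The four tissue classes
#'
#' Fixed ordering used throughout the package (and by the classifier
#' cascade): white/lumen, stroma, nuclei, cytoplasm.
#'
#' @return character vector of the four class names.
#' @export
tissue_classes <- function() c("white", "stroma", "nuclei", "cytoplasm")

UNASSIGNED <- "unassigned"

#' Create a cluster-to-structure assignment
#'
#' Associates each color cluster with one of the four tissue elements or
#' leaves it unassigned (for colors shared by several structures).  This is
#' the programmatic counterpart of highlighting palette colors over the
#' image and labeling the ones that clearly belong to a single structure.
#'
#' @param mapping named character vector (or list); names are 0-based
#'   cluster ids `"0" ... "k-1"`, values one of
#'   `"white", "stroma", "nuclei", "cytoplasm", "unassigned"`.
#' @param k number of clusters the assignment must cover.
#' @return object of class `color_assignment` (named character vector with
#'   attribute `k`).
#' @export
color_assignment <- function(mapping, k) {
  mapping <- unlist(mapping)
  validate_assignment(mapping, k)
  structure(mapping[as.character(0:(k - 1L))], k = as.integer(k),
            class = "color_assignment")
}

validate_assignment <- function(mapping, k) {
  expected <- as.character(0:(k - 1L))
  missing <- setdiff(expected, names(mapping))
  if (length(missing))
    stop("assignment missing cluster id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(mapping), expected)
  if (length(extra))
    stop("assignment has unknown cluster id(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(mapping), c(tissue_classes(), UNASSIGNED))
  if (length(bad))
    stop("unknown class name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  uncovered <- setdiff(tissue_classes(), mapping)
  if (length(uncovered))
    stop("class(es) with no assigned cluster: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Load / write a color assignment JSON file
#'
#' Schema: `{"k": int, "assignment": {"<cluster_id>": "white|stroma|nuclei|
#' cytoplasm|unassigned", ...}}` with 0-based cluster ids.
#'
#' @param path JSON file path.
#' @return a `color_assignment`.
#' @export
load_assignment <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$k) || is.null(j$assignment))
    stop("assignment file must contain fields 'k' and 'assignment'",
         call. = FALSE)
  color_assignment(j$assignment, as.integer(j$k))
}

#' @param assignment a `color_assignment`.
#' @rdname load_assignment
#' @export
write_assignment <- function(assignment, path) {
  k <- attr(assignment, "k")
  jsonlite::write_json(list(k = k, assignment = as.list(assignment)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Build the labeled training set from assigned clusters
#'
#' Every pixel of every assigned cluster becomes a labeled Cartesian-HSV
#' training point; unassigned clusters contribute nothing.  These labels
#' serve as ground truth for the classifier cascade.
#'
#' @param clustered a [reduce_colors()] result.
#' @param assignment a `color_assignment` with matching `k`.
#' @return object of class `training_set`: `x` (`n x 3` Cartesian matrix),
#'   `y` (factor over the four classes), `counts` per class.
#' @export
build_training_set <- function(clustered, assignment) {
  stopifnot(inherits(clustered, "clustered_image"),
            inherits(assignment, "color_assignment"))
  if (attr(assignment, "k") != clustered$k)
    stop("assignment covers k = ", attr(assignment, "k"),
         " clusters but image has k = ", clustered$k, call. = FALSE)
  lab <- as.vector(clustered$labels)
  cls_of_cluster <- unname(assignment[as.character(lab)])
  keep <- cls_of_cluster != UNASSIGNED
  y <- factor(cls_of_cluster[keep], levels = tissue_classes())
  counts <- table(y)
  if (any(counts == 0))
    stop("no training pixels for class(es): ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  structure(list(x = clustered$points[keep, , drop = FALSE], y = y,
                 counts = counts),
            class = "training_set")
}

#' Assign clusters from a ground-truth label map
#'
#' Emulates an annotator who labels only colors belonging to a single
#' tissue element: a cluster is assigned to a class when at least
#' `purity_threshold` of its pixels carry that ground-truth class, and left
#' unassigned otherwise.  Intended for synthetic tiles, where the truth
#' raster comes from the generator.
#'
#' @param clustered a [reduce_colors()] result.
#' @param truth integer `H x W` raster of ground-truth classes (1 = white,
#'   2 = stroma, 3 = nuclei, 4 = cytoplasm), aligned with the image.
#' @param purity_threshold required majority fraction, in `(0.5, 1]`
#'   (default 0.9).
#' @return a `color_assignment`.
#' @export
auto_assign <- function(clustered, truth, purity_threshold = 0.9) {
  stopifnot(inherits(clustered, "clustered_image"))
  if (purity_threshold <= 0.5 || purity_threshold > 1)
    stop("purity_threshold must lie in (0.5, 1]", call. = FALSE)
  if (!all(dim(truth) == dim(clustered$labels)))
    stop("truth raster does not align with the clustered labels",
         call. = FALSE)
  lab <- as.vector(clustered$labels)
  tr <- as.integer(truth)
  cls <- tissue_classes()
  mapping <- vapply(0:(clustered$k - 1L), function(c) {
    tab <- tabulate(tr[lab == c], nbins = 4L)
    tot <- sum(tab)
    if (tot == 0L) return(UNASSIGNED)
    if (max(tab) / tot >= purity_threshold) cls[which.max(tab)] else UNASSIGNED
  }, character(1))
  names(mapping) <- as.character(0:(clustered$k - 1L))
  uncovered <- setdiff(cls, mapping)
  if (length(uncovered))
    stop("auto-assignment left class(es) without a cluster: ",
         paste(uncovered, collapse = ", "),
         "; consider lowering purity_threshold", call. = FALSE)
  color_assignment(mapping, clustered$k)
}
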