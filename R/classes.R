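# S3 value classes shared across the pipeline.
#
# Array convention (fixed throughout the package): voxel arrays have
# dim = c(ny, nx, nz); vol[y, x, z].  Axial orientation, radiological
# display: slice z = 1 is the most superior; rows y increase
# anterior -> posterior (patient front at the top of the image); columns
# x increase patient-right -> patient-left (patient left at image right).
# Indices are 1-based and bounding boxes are inclusive c(y0, y1, x0, x1).
# `spacing` is a named numeric c(z, y, x) in millimetres.

new_volume <- function(voxels, spacing, class, extra = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (y, x, z)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (z, y, x)", call. = FALSE)
  names(spacing) <- c("z", "y", "x")
  structure(c(list(voxels = voxels, spacing = spacing), extra), class = class)
}

#' CT volume in Hounsfield units
#'
#' Container for an axial CT stack.  Voxels are integers in HU; `spacing`
#' gives the (z, y, x) voxel size in mm.  Slice 1 is the most superior;
#' rows run anterior to posterior and columns patient-right to patient-left
#' (radiological display).
#'
#' @param voxels 3D integer array, `dim = c(ny, nx, nz)`, indexed `[y, x, z]`.
#' @param spacing numeric length 3, voxel size in mm as `c(z, y, x)`.
#' @return An object of class `ct_volume` with elements `voxels` and `spacing`.
#' @export
ct_volume <- function(voxels, spacing) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "integer"
  new_volume(voxels, spacing, c("ct_volume", "volume3d"))
}

#' Windowed (8-bit) volume
#'
#' A CT volume after window width/level mapping to display gray levels
#' 0..255.  Created by [apply_window()].
#'
#' @param voxels 3D integer array with values in 0..255.
#' @param spacing voxel size in mm, `c(z, y, x)`.
#' @param width,level window width and level in HU.
#' @return An object of class `windowed_volume`.
#' @export
windowed_volume <- function(voxels, spacing, width, level) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "integer"
  if (min(voxels) < 0L || max(voxels) > 255L)
    stop("windowed voxels must lie in [0, 255]", call. = FALSE)
  new_volume(voxels, spacing, c("windowed_volume", "volume3d"),
             list(width = as.numeric(width), level = as.numeric(level)))
}

#' Binary volume over {0, 255}
#'
#' @param voxels 3D integer array whose values are exactly 0 or 255.
#' @param spacing voxel size in mm, `c(z, y, x)`.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, spacing) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "integer"
  if (!all(voxels == 0L | voxels == 255L))
    stop("binary voxels must be exactly 0 or 255", call. = FALSE)
  new_volume(voxels, spacing, c("binary_volume", "volume3d"))
}

#' Integer label volume
#'
#' Non-negative integer labels per voxel; 0 is background and the nonzero
#' labels form the contiguous set 1..`label_count`.
#'
#' @param voxels 3D integer array of labels.
#' @param spacing voxel size in mm, `c(z, y, x)`.
#' @return An object of class `label_volume` with a `label_count` element.
#' @export
label_volume <- function(voxels, spacing) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "integer"
  labs <- sort(unique(voxels[voxels > 0L]))
  n <- length(labs)
  if (n > 0L && !identical(labs, seq_len(n)))
    stop("nonzero labels must form the contiguous set 1..label_count", call. = FALSE)
  if (min(voxels) < 0L) stop("labels must be non-negative", call. = FALSE)
  new_volume(voxels, spacing, c("label_volume", "volume3d"),
             list(label_count = n))
}

#' Ribs-only mask with provenance
#'
#' A binary volume restricted to rib voxels, together with the per-slice
#' vertebra detections that produced it and a log of everything removed.
#'
#' @param volume a [binary_volume()].
#' @param detections list (length nz) of vertebra detections or `NULL`s.
#' @param removed provenance list of erased/excluded regions.
#' @return An object of class `rib_mask`.
#' @export
rib_mask <- function(volume, detections = vector("list", dim(volume$voxels)[3]),
                     removed = list()) {
  stopifnot(inherits(volume, "binary_volume"))
  structure(list(volume = volume, detections = detections, removed = removed),
            class = "rib_mask")
}

#' Vertebra template library
#'
#' An ordered set of small 8-bit grayscale patches depicting thoracic
#' vertebra cross-sections, used by [match_vertebra()].  The tight bounding
#' box and pixel count of each patch's foreground (value 255) are
#' precomputed; they define the detected vertebral region when a template
#' matches.
#'
#' @param templates list of numeric matrices with values in 0..255.
#' @param ids character vector of template identifiers (default names or
#'   `tpl01`, `tpl02`, ...).
#' @return An object of class `template_set`.
#' @export
template_set <- function(templates, ids = NULL) {
  if (length(templates) == 0L) stop("template set must be non-empty", call. = FALSE)
  templates <- lapply(templates, function(t) {
    t <- as.matrix(t); storage.mode(t) <- "integer"
    if (min(t) < 0L || max(t) > 255L) stop("template values must lie in [0, 255]", call. = FALSE)
    t
  })
  if (is.null(ids)) ids <- sprintf("tpl%02d", seq_along(templates))
  fg <- lapply(templates, function(t) {
    w <- which(t == 255L, arr.ind = TRUE)
    if (nrow(w) == 0L) list(box = c(1L, nrow(t), 1L, ncol(t)), count = 0L)
    else list(box = c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2])),
              count = nrow(w))
  })
  structure(list(templates = templates, ids = as.character(ids),
                 fg_box = lapply(fg, `[[`, "box"),
                 fg_count = vapply(fg, `[[`, integer(1), "count")),
            class = "template_set")
}

# inclusive box helpers ------------------------------------------------------

clip_box <- function(box, ny, nx) {
  c(max(box[1], 1L), min(box[2], ny), max(box[3], 1L), min(box[4], nx))
}

box_valid <- function(box) box[1] <= box[2] && box[3] <= box[4]

expand_box <- function(box, m) c(box[1] - m, box[2] + m, box[3] - m, box[4] + m)

same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

# print methods --------------------------------------------------------------

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %d x %d x %d voxels (y, x, z), spacing %.3f x %.3f x %.3f mm (z, y, x)\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing["z"], x$spacing["y"], x$spacing["x"]))
  if (inherits(x, "windowed_volume"))
    cat(sprintf("  window width %g HU, level %g HU\n", x$width, x$level))
  if (inherits(x, "label_volume"))
    cat(sprintf("  %d nonzero labels\n", x$label_count))
  invisible(x)
}

#' @export
print.rib_mask <- function(x, ...) {
  d <- dim(x$volume$voxels)
  ndet <- sum(!vapply(x$detections, is.null, logical(1)))
  cat(sprintf("<rib_mask> %d x %d x %d, %d foreground voxels, %d slice detections\n",
              d[1], d[2], d[3], sum(x$volume$voxels == 255L), ndet))
  invisible(x)
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates: %s\n", length(x$templates),
              paste(x$ids, collapse = ", ")))
  invisible(x)
}
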