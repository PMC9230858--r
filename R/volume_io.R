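# Reading/writing volumes, intensity windowing, in-plane resampling,
# report and overlay output.

#' Read a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file into a [ct_volume()].  The array is taken
#' in the package's axial convention (slice 1 most superior, rows
#' anterior to posterior, columns patient-right to patient-left); voxel
#' spacing comes from the NIfTI header.  DICOM series directories are not
#' supported by this build and raise a format error.
#'
#' @param path path to a NIfTI file.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  arr <- read_nifti_array(path)
  ct_volume(arr$voxels, arr$spacing)
}

#' Read a binary mask volume from NIfTI
#'
#' Any nonzero voxel becomes 255, so masks written by other segmenters
#' (e.g. 0/1 coded CNN output) are accepted as-is.
#'
#' @param path path to a NIfTI file.
#' @return A [binary_volume()].
#' @export
read_binary_volume <- function(path) {
  arr <- read_nifti_array(path)
  v <- arr$voxels
  v[] <- ifelse(v != 0L, 255L, 0L)
  binary_volume(v, arr$spacing)
}

#' Read an integer label volume from NIfTI
#'
#' @param path path to a NIfTI file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  arr <- read_nifti_array(path)
  label_volume(arr$voxels, arr$spacing)
}

#' Ingest an externally produced rib mask
#'
#' Wraps any binary rib mask (from a CNN or other segmenter) as a
#' [rib_mask()] with empty provenance, so it can feed [label_sequence()]
#' directly.
#'
#' @param path path to a NIfTI mask file.
#' @return A [rib_mask()].
#' @export
read_rib_mask <- function(path) rib_mask(read_binary_volume(path))

read_nifti_array <- function(path) {
  if (dir.exists(path))
    stop(sprintf("format error: '%s' is a directory; DICOM series input is not supported, convert to NIfTI first", path),
         call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("format error: no such file '%s'", path), call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf("format error reading '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  v <- as.array(img)
  v <- array(as.vector(v), dim(v))  # plain array, header attributes dropped
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  if (length(dim(v)) != 3L)
    stop(sprintf("format error: '%s' is not a 3D volume", path), call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 2L || any(!is.finite(pd[seq_len(min(3, length(pd)))])) ||
      any(pd[seq_len(min(3, length(pd)))] <= 0))
    stop(sprintf("format error: '%s' has missing or non-positive voxel spacing", path),
         call. = FALSE)
  if (length(pd) < 3L) pd <- c(pd, 1)
  storage.mode(v) <- "integer"
  # stored dims are (y, x, z), so pixdim slots 1..3 are (dy, dx, dz)
  list(voxels = v, spacing = c(z = pd[3], y = pd[1], x = pd[2]))
}

write_nifti_array <- function(voxels, spacing, path, datatype) {
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- c(spacing["y"], spacing["x"], spacing["z"])
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write volumes to NIfTI
#'
#' `write_ct_volume()` stores HU as int16; `write_binary_volume()` and
#' `write_label_volume()` store uint8.
#'
#' @param vol,bin,lab the volume to write.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  write_nifti_array(vol$voxels, vol$spacing, path, "int16")
}

#' @rdname write_ct_volume
#' @export
write_binary_volume <- function(bin, path) {
  stopifnot(inherits(bin, "binary_volume"))
  write_nifti_array(bin$voxels, bin$spacing, path, "uint8")
}

#' @rdname write_ct_volume
#' @export
write_label_volume <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  write_nifti_array(lab$voxels, lab$spacing, path, "uint8")
}

#' Apply a display window to a CT volume
#'
#' Linear window width/level mapping of HU to 8-bit gray.  HU at or below
#' `level - width/2` map to 0, at or above `level + width/2` map to 255,
#' linear in between with half-up rounding.  Defaults emphasize bone
#' against soft tissue on chest CT.
#'
#' @param vol a [ct_volume()].
#' @param width window width in HU (> 0); default 400.
#' @param level window level in HU; default 40.
#' @return A [windowed_volume()].
#' @examples
#' v <- ct_volume(array(c(-160L, 40L, 240L), c(1, 1, 3)), c(1, 1, 1))
#' apply_window(v)$voxels[1, 1, ]  # 0 128 255
#' @export
apply_window <- function(vol, width = 400, level = 40) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.numeric(width) || width <= 0)
    stop("parameter error: window width must be > 0", call. = FALSE)
  lo <- level - width / 2
  g <- (vol$voxels - lo) / width * 255
  g <- pmin(pmax(g, 0), 255)
  g[] <- floor(g + 0.5)  # round half-up
  storage.mode(g) <- "integer"
  windowed_volume(g, vol$spacing, width, level)
}

#' Resample a volume in-plane to a target pixel spacing
#'
#' Unifies the in-plane (y, x) pixel spacing; slice spacing is never
#' changed.  Intensity volumes are interpolated bilinearly; binary and
#' label volumes use nearest-neighbour so no new values are created.  New
#' in-plane dimensions are `round(old * old_spacing / target)`.  A volume
#' already at the target spacing is returned unchanged.
#'
#' @param vol a [ct_volume()], [windowed_volume()], [binary_volume()] or
#'   [label_volume()].
#' @param target_spacing target in-plane pixel spacing in mm (default the
#'   cohort-unified 0.798 mm).
#' @return A volume of the same class at the target spacing.
#' @export
resample_inplane <- function(vol, target_spacing = 0.798) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("parameter error: target_spacing must be > 0", call. = FALSE)
  sp <- vol$spacing
  if (abs(sp["y"] - target_spacing) < 1e-4 && abs(sp["x"] - target_spacing) < 1e-4)
    return(vol)
  d <- dim(vol$voxels)
  ny2 <- max(1L, as.integer(round(d[1] * sp["y"] / target_spacing)))
  nx2 <- max(1L, as.integer(round(d[2] * sp["x"] / target_spacing)))
  nearest <- inherits(vol, "binary_volume") || inherits(vol, "label_volume")
  out <- array(0L, c(ny2, nx2, d[3]))
  # map output pixel centers to input coordinates (1-based)
  sy <- (seq_len(ny2) - 0.5) * d[1] / ny2 + 0.5 - 0.5
  sx <- (seq_len(nx2) - 0.5) * d[2] / nx2 + 0.5 - 0.5
  if (nearest) {
    iy <- pmin(pmax(round(sy), 1L), d[1])
    ix <- pmin(pmax(round(sx), 1L), d[2])
    for (z in seq_len(d[3])) out[, , z] <- vol$voxels[iy, ix, z]
  } else {
    y0 <- pmin(pmax(floor(sy), 1L), d[1]); y1 <- pmin(y0 + 1L, d[1])
    x0 <- pmin(pmax(floor(sx), 1L), d[2]); x1 <- pmin(x0 + 1L, d[2])
    wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
    WY1 <- matrix(1 - wy, ny2, nx2); WY2 <- matrix(wy, ny2, nx2)
    WX1 <- matrix(1 - wx, ny2, nx2, byrow = TRUE); WX2 <- matrix(wx, ny2, nx2, byrow = TRUE)
    for (z in seq_len(d[3])) {
      s <- vol$voxels[, , z]
      g <- WY1 * (WX1 * s[y0, x0] + WX2 * s[y0, x1]) +
           WY2 * (WX1 * s[y1, x0] + WX2 * s[y1, x1])
      out[, , z] <- as.integer(round(g))
    }
  }
  newsp <- c(z = unname(sp["z"]), y = target_spacing, x = target_spacing)
  switch(class(vol)[1],
         ct_volume = ct_volume(out, newsp),
         windowed_volume = windowed_volume(out, newsp, vol$width, vol$level),
         binary_volume = binary_volume(out, newsp),
         label_volume = label_volume(out, newsp))
}

#' Write a JSON report
#'
#' Serializes a rib label report, case result, cohort result or any
#' list-like report to pretty-printed JSON.
#'
#' @param report the report object.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  cls <- class(report)[1]
  x <- unclass(report)
  x$.class <- cls
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", digits = NA, na = "null")
  invisible(path)
}

#' Write per-slice PNG overlays
#'
#' Renders each axial slice of the windowed volume as grayscale with
#' labeled voxels colored by label, and (when a report is supplied) the
#' ordinal number drawn near each left rib's annotation position.
#'
#' @param win a [windowed_volume()].
#' @param lab a [label_volume()] with matching geometry.
#' @param dir output directory (created if needed).
#' @param report optional rib label report supplying annotations.
#' @return Character vector of PNG paths, invisibly.
#' @export
write_overlays <- function(win, lab, dir, report = NULL) {
  stopifnot(inherits(win, "windowed_volume"), inherits(lab, "label_volume"))
  if (!same_geometry(win, lab))
    stop("parameter error: label volume geometry does not match windowed volume", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(win$voxels)
  nlab <- max(1L, lab$label_count)
  pal <- grDevices::hsv(h = (seq_len(nlab) - 1) / nlab, s = 1, v = 1)
  palrgb <- grDevices::col2rgb(pal) / 255
  ann <- if (!is.null(report) && NROW(report$annotations) > 0) report$annotations else NULL
  paths <- character(d[3])
  for (z in seq_len(d[3])) {
    g <- win$voxels[, , z] / 255
    rgb <- array(g, c(d[1], d[2], 3))
    lz <- lab$voxels[, , z]
    sel <- which(lz > 0L)
    if (length(sel)) {
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[sel] <- palrgb[ch, lz[sel]]
        rgb[, , ch] <- plane
      }
    }
    if (!is.null(ann)) {
      az <- ann[ann$z == z, , drop = FALSE]
      for (i in seq_len(nrow(az)))
        rgb <- draw_number(rgb, az$ordinal[i], az$y[i], az$x[i] + 4L)
    }
    paths[z] <- file.path(dir, sprintf("slice_%03d.png", z))
    png::writePNG(rgb, paths[z])
  }
  invisible(paths)
}

# 3x5 bitmap digit font for overlay annotations ------------------------------

digit_font <- local({
  rows <- c("111101101101111",  # 0
            "010110010010111",  # 1
            "111001111100111",  # 2
            "111001111001111",  # 3
            "101101111001001",  # 4
            "111100111001111",  # 5
            "111100111101111",  # 6
            "111001001001001",  # 7
            "111101111101111",  # 8
            "111101111001111")  # 9
  lapply(rows, function(r) matrix(as.integer(strsplit(r, "")[[1]]) == 1L,
                                  nrow = 5, ncol = 3, byrow = TRUE))
})

draw_number <- function(rgb, num, y, x, scale = 2L) {
  digits <- as.integer(strsplit(as.character(num), "")[[1]])
  d <- dim(rgb)
  xoff <- 0L
  for (dg in digits) {
    glyph <- digit_font[[dg + 1L]]
    glyph <- glyph[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale)]
    px <- which(glyph, arr.ind = TRUE)
    yy <- y - 5L + px[, 1]
    xx <- x + xoff + px[, 2]
    ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2]
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[cbind(yy[ok], xx[ok])] <- 1
      rgb[, , ch] <- plane
    }
    xoff <- xoff + 3L * scale + scale
  }
  rgb
}
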