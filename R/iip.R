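# Intensity-based image processing (IIP) rib mask extraction:
# binarize -> per-slice SAD template matching -> vertebra/sternum zero
# padding -> morphological bed/noise removal -> vertebra-contact filtering
# of region-grown objects.  No stage ever adds a foreground voxel.

#' IIP pipeline configuration
#'
#' @param threshold binarization threshold on the 8-bit windowed image;
#'   pixels strictly greater are kept (default 140, above the midpoint of
#'   the display range).
#' @param erase_margin pixels by which the detected vertebral region is
#'   expanded before zero padding (default 0).
#' @param sternum_scale height of the reflected sternum erase box as a
#'   multiple of the vertebra box height (default 2; only the width is
#'   tied to the detection).
#' @param contact_margin maximum Chebyshev distance (pixels) from the
#'   vertebra box at which an object still counts as "in contact"
#'   (default 3).
#' @param bed_band height (pixels) of the posterior border band used by
#'   the bed heuristic (default 10).
#' @param opening_radius disk radius of the per-slice morphological
#'   opening (default 1; 0 disables).
#' @param min_size minimum 2D object size in pixels (default 20).
#' @param sad_ceiling SAD score above which a slice's match is deemed
#'   unreliable and the nearest superior detection is reused.  `NULL`
#'   (default) uses the automatic rule: reliable iff
#'   `score < 0.5 * 255 * template_foreground_count`.
#' @param search_posterior restrict template search to the posterior half
#'   of each slice (vertebrae are posterior); `FALSE` searches the whole
#'   slice.
#' @param missing_vertebra `"error"` or `"warn"`: behaviour when no
#'   reliable vertebra detection exists anywhere in the volume.
#' @return A list of class `iip_config`.
#' @export
iip_config <- function(threshold = 140L, erase_margin = 0L, sternum_scale = 2,
                       contact_margin = 3L, bed_band = 10L,
                       opening_radius = 1L, min_size = 20L,
                       sad_ceiling = NULL, search_posterior = TRUE,
                       missing_vertebra = c("error", "warn")) {
  structure(list(threshold = as.integer(threshold),
                 erase_margin = as.integer(erase_margin),
                 sternum_scale = sternum_scale,
                 contact_margin = as.integer(contact_margin),
                 bed_band = as.integer(bed_band),
                 opening_radius = as.integer(opening_radius),
                 min_size = as.integer(min_size),
                 sad_ceiling = sad_ceiling,
                 search_posterior = isTRUE(search_posterior),
                 missing_vertebra = match.arg(missing_vertebra)),
            class = "iip_config")
}

#' Load a pipeline configuration from a YAML key-value file
#'
#' Keys absent from the file keep their [iip_config()] defaults; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return An `iip_config`.
#' @export
load_iip_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(iip_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("parameter error: unknown config keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(iip_config, vals)
}

#' Binarize a windowed volume
#'
#' Voxels strictly greater than the threshold become 255 (bone); all
#' others become 0.
#'
#' @param win a [windowed_volume()].
#' @param threshold intensity threshold in 0..255 (default 140).
#' @return A [binary_volume()].
#' @export
binarize <- function(win, threshold = 140L) {
  stopifnot(inherits(win, "windowed_volume"))
  if (threshold < 0 || threshold > 255)
    stop("parameter error: threshold must lie in [0, 255]", call. = FALSE)
  v <- win$voxels
  v[] <- ifelse(v > threshold, 255L, 0L)
  binary_volume(v, win$spacing)
}

#' Sum of absolute differences at one placement
#'
#' The SAD score between a template and the image patch under it:
#' `sum(|image - template|)` over the template extent, as an exact
#' integer.  Zero iff the patch equals the template exactly.
#'
#' @param image numeric matrix (target slice).
#' @param template numeric matrix, strictly smaller than or equal to the
#'   image in both dimensions when placed at `origin`.
#' @param origin integer `c(u, v)`: 1-based (row, column) of the
#'   template's top-left placement.
#' @return Integer SAD score.
#' @export
sad <- function(image, template, origin = c(1L, 1L)) {
  u <- as.integer(origin[1]); v <- as.integer(origin[2])
  th <- nrow(template); tw <- ncol(template)
  if (u < 1L || v < 1L || u + th - 1L > nrow(image) || v + tw - 1L > ncol(image))
    stop("parameter error: template overhangs image", call. = FALSE)
  sum(abs(image[u:(u + th - 1L), v:(v + tw - 1L)] - template))
}

# integral-image window sums of a 0/1 matrix for a (th, tw) window
window_sums <- function(bin01, th, tw) {
  ny <- nrow(bin01); nx <- ncol(bin01)
  S <- matrix(0, ny + 1L, nx + 1L)
  S[-1, -1] <- t(apply(apply(bin01, 2, cumsum), 1, cumsum))
  nu <- ny - th + 1L; nv <- nx - tw + 1L
  S[(1L + th):(ny + 1L), (1L + tw):(nx + 1L), drop = FALSE] -
    S[1:nu, (1L + tw):(nx + 1L), drop = FALSE] -
    S[(1L + th):(ny + 1L), 1:nv, drop = FALSE] +
    S[1:nu, 1:nv, drop = FALSE]
}

# cross-correlation of 0/1 image with 0/1 template via FFT; element [u, v]
# is the overlap count for the template placed at origin (u, v)
xcorr_counts <- function(fft_img, tpl01, dims) {
  Temb <- matrix(0, dims[1], dims[2])
  Temb[seq_len(nrow(tpl01)), seq_len(ncol(tpl01))] <- tpl01
  r <- Re(stats::fft(fft_img * Conj(stats::fft(Temb)), inverse = TRUE)) / prod(dims)
  round(r)
}

# precompute per-volume matching state for one subregion size
match_precompute <- function(dims) new.env(parent = emptyenv())

#' Find the best-matching vertebra template on a slice
#'
#' Slides every template over every valid placement inside the search
#' region and returns the placement minimizing the SAD score.  Ties are
#' broken by smaller template id, then raster order of position.  For
#' binary slices and templates the exact score map is computed by the
#' identity `SAD = 255 * (window_fg + template_fg - 2 * overlap)` using
#' integral images and FFT cross-correlation; grayscale inputs fall back
#' to direct summation.
#'
#' @param slice integer matrix (a binary or windowed slice).
#' @param templates a [template_set()].
#' @param search_box optional inclusive `c(y0, y1, x0, x1)` region within
#'   which the template placement must lie; default the whole slice.
#' @return A `vertebra_detection`: list with `slice_index` (`NA` until set
#'   by the caller), `origin` `(u, v)`, `template_id`, `score`, `box`
#'   (tight bounding box of the matched template's foreground, i.e. the
#'   detected vertebral region) and `match_box` (full patch footprint).
#' @export
match_vertebra <- function(slice, templates, search_box = NULL) {
  stopifnot(is.matrix(slice))
  if (!inherits(templates, "template_set"))
    stop("parameter error: templates must be a template_set", call. = FALSE)
  ny <- nrow(slice); nx <- ncol(slice)
  if (is.null(search_box)) search_box <- c(1L, ny, 1L, nx)
  sb <- clip_box(as.integer(search_box), ny, nx)
  sub <- slice[sb[1]:sb[2], sb[3]:sb[4], drop = FALSE]
  sh <- nrow(sub); sw <- ncol(sub)
  binary <- all(sub == 0L | sub == 255L) &&
    all(vapply(templates$templates, function(t) all(t == 0L | t == 255L), logical(1)))
  fft_img <- if (binary) stats::fft(sub / 255) else NULL
  best <- NULL
  any_fit <- FALSE
  for (i in seq_along(templates$templates)) {
    tpl <- templates$templates[[i]]
    th <- nrow(tpl); tw <- ncol(tpl)
    if (th > sh || tw > sw) next
    any_fit <- TRUE
    if (binary) {
      W <- window_sums(sub / 255, th, tw)
      ov <- xcorr_counts(fft_img, tpl / 255, c(sh, sw))[seq_len(sh - th + 1L),
                                                       seq_len(sw - tw + 1L), drop = FALSE]
      sadmap <- 255 * (W + templates$fg_count[i] - 2 * ov)
    } else {
      nu <- sh - th + 1L; nv <- sw - tw + 1L
      sadmap <- matrix(0, nu, nv)
      for (v in seq_len(nv)) for (u in seq_len(nu))
        sadmap[u, v] <- sum(abs(sub[u:(u + th - 1L), v:(v + tw - 1L)] - tpl))
    }
    m <- min(sadmap)
    if (is.null(best) || m < best$score) {
      hit <- which(sadmap == m, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]  # raster order
      u <- sb[1] + hit[1] - 1L; v <- sb[3] + hit[2] - 1L
      fgb <- templates$fg_box[[i]]
      best <- list(slice_index = NA_integer_,
                   origin = c(u = u, v = v),
                   template_id = templates$ids[i],
                   template_index = i,
                   score = as.integer(round(m)),
                   box = c(u + fgb[1] - 1L, u + fgb[2] - 1L,
                           v + fgb[3] - 1L, v + fgb[4] - 1L),
                   match_box = c(u, u + th - 1L, v, v + tw - 1L))
      class(best) <- "vertebra_detection"
    }
  }
  if (!any_fit)
    stop("parameter error: no template fits within the search region", call. = FALSE)
  best
}

#' @export
print.vertebra_detection <- function(x, ...) {
  cat(sprintf("<vertebra_detection> slice %s: template %s at (%d, %d), score %d\n",
              ifelse(is.na(x$slice_index), "?", x$slice_index),
              x$template_id, x$origin["u"], x$origin["v"], x$score))
  invisible(x)
}

#' Zero-pad the vertebral and sternum regions on a slice
#'
#' Zeroes all pixels inside the detected vertebral box (expanded by
#' `margin`), then zeroes a sternum box of the same width whose center is
#' the vertebra box center reflected across the body center row along the
#' anterior-posterior axis (the two bones face each other across the
#' thorax).  Both boxes are clipped to the slice.
#'
#' @param slice integer matrix over \{0, 255\}.
#' @param det a `vertebra_detection` for this slice.
#' @param body_centroid_y body center row used as the reflection axis.
#' @param margin expansion of the vertebra box in pixels (default 0).
#' @param sternum_scale sternum box height as a multiple of the vertebra
#'   box height (default 2).
#' @return List: `slice` (modified), `vertebra_box`, `sternum_box`
#'   (each the clipped inclusive box actually erased, or `NULL` if off
#'   the slice).
#' @export
erase_vertebra_sternum <- function(slice, det, body_centroid_y,
                                   margin = 0L, sternum_scale = 2) {
  ny <- nrow(slice); nx <- ncol(slice)
  vb <- clip_box(expand_box(det$box, as.integer(margin)), ny, nx)
  if (box_valid(vb)) slice[vb[1]:vb[2], vb[3]:vb[4]] <- 0L else vb <- NULL
  vcy <- (det$box[1] + det$box[2]) / 2
  scy <- 2 * body_centroid_y - vcy
  h <- max(1L, round((det$box[2] - det$box[1] + 1L) * sternum_scale))
  sbx <- c(round(scy - h / 2), round(scy - h / 2) + h - 1L,
           det$box[3] - as.integer(margin), det$box[4] + as.integer(margin))
  sbx <- clip_box(sbx, ny, nx)
  if (box_valid(sbx)) slice[sbx[1]:sbx[2], sbx[3]:sbx[4]] <- 0L else sbx <- NULL
  list(slice = slice, vertebra_box = vb, sternum_box = sbx)
}

#' Morphological bed and noise removal
#'
#' Per slice: morphological opening with a disk, removal of 2D
#' four-connected objects below `min_size` pixels, and removal of objects
#' whose bounding box touches the posterior border band (the scanner bed
#' heuristic).  Foreground is only ever removed, never added.
#'
#' @param vol a [binary_volume()].
#' @param min_size minimum object size in pixels.
#' @param opening_radius disk radius for the opening (0 disables).
#' @param bed_band posterior border band height in pixels (0 disables).
#' @return A [binary_volume()].
#' @export
remove_bed_and_noise <- function(vol, min_size = 20L, opening_radius = 1L,
                                 bed_band = 10L) {
  stopifnot(inherits(vol, "binary_volume"))
  d <- dim(vol$voxels)
  fg <- vol$voxels == 255L
  if (opening_radius >= 1L) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, "disc")
    fg <- EBImage::opening(fg * 1, brush) > 0.5
    dim(fg) <- d
  }
  band_start <- d[1] - bed_band + 1L
  for (z in seq_len(d[3])) {
    sl <- fg[, , z]
    if (!any(sl)) next
    regions <- label_components_2d(sl)
    for (lin in regions) {
      drop <- length(lin) < min_size
      if (!drop && bed_band > 0L) {
        ymax <- max((lin - 1L) %% d[1] + 1L)
        drop <- ymax >= band_start
      }
      if (drop) sl[lin] <- FALSE
    }
    fg[, , z] <- sl
  }
  binary_volume(array(ifelse(fg, 255L, 0L), d), vol$spacing)
}

#' Exclude objects not in contact with the vertebral region
#'
#' Links 2D regions across consecutive slices by pixel overlap into 3D
#' objects (equivalently, six-connected components).  An object is kept
#' iff, on its first slice of appearance, at least one pixel lies within
#' `contact_margin` (Chebyshev distance) of the vertebra box logged for
#' that slice; everything else is zeroed and logged.
#'
#' @param vol a [binary_volume()] (after erasure and cleanup).
#' @param detections list (length nz) of `vertebra_detection` or `NULL`;
#'   slices without a detection reuse the nearest superior one.
#' @param contact_margin Chebyshev contact distance in pixels (default 3).
#' @return A [rib_mask()] whose `removed$filtered` logs excluded objects.
#' @export
filter_nonrib_objects <- function(vol, detections, contact_margin = 3L) {
  stopifnot(inherits(vol, "binary_volume"))
  d <- dim(vol$voxels)
  comps <- label_components_3d(vol$voxels == 255L)
  keepvox <- array(FALSE, d)
  removed <- list()
  for (cl in comps$clusters) {
    fz <- cl$first_slice
    det <- NULL
    for (z in fz:1) {
      if (z <= length(detections) && !is.null(detections[[z]])) { det <- detections[[z]]; break }
    }
    if (is.null(det))
      stop(sprintf("processing error: no vertebra detection available for slice %d", fz),
           call. = FALSE)
    co <- lin_to_zyx(cl$lin, d)
    co <- co[co[, "z"] == fz, , drop = FALSE]
    b <- det$box
    dy <- pmax(b[1] - co[, "y"], co[, "y"] - b[2], 0)
    dx <- pmax(b[3] - co[, "x"], co[, "x"] - b[4], 0)
    if (min(pmax(dy, dx)) <= contact_margin) {
      keepvox[cl$lin] <- TRUE
    } else {
      removed[[length(removed) + 1L]] <-
        list(first_slice = fz, size = cl$size, seed = cl$seed,
             reason = "no vertebral contact at first appearance")
    }
  }
  out <- binary_volume(array(ifelse(keepvox, 255L, 0L), d), vol$spacing)
  rib_mask(out, detections, removed = list(filtered = removed))
}

#' Build a ribs-only mask by intensity-based image processing
#'
#' Orchestrates the full IIP pipeline: binarization, per-slice vertebra
#' template matching, vertebra/sternum zero padding, morphological bed and
#' noise removal, and vertebra-contact filtering of the region-grown 3D
#' objects.  Returns a [rib_mask()] with full provenance (per-slice
#' detections, erased boxes, per-stage foreground counts, filtered
#' objects).
#'
#' @param win a [windowed_volume()].
#' @param templates a [template_set()].
#' @param config an [iip_config()].
#' @return A [rib_mask()].
#' @export
build_iip_mask <- function(win, templates, config = iip_config()) {
  stopifnot(inherits(win, "windowed_volume"))
  cfg <- config
  d <- dim(win$voxels)
  bin <- binarize(win, cfg$threshold)
  search_box <- if (cfg$search_posterior)
    c(floor(d[1] / 2) + 1L, d[1], 1L, d[2]) else NULL

  detections <- vector("list", d[3])
  last_reliable <- NULL
  for (z in seq_len(d[3])) {
    det <- match_vertebra(bin$voxels[, , z], templates, search_box)
    ceiling_z <- if (is.null(cfg$sad_ceiling))
      0.5 * 255 * templates$fg_count[det$template_index] else cfg$sad_ceiling
    if (det$score < ceiling_z) {
      det$slice_index <- z
      last_reliable <- det
      detections[[z]] <- det
    } else if (!is.null(last_reliable)) {
      inh <- last_reliable
      inh$inherited_from <- inh$slice_index
      inh$slice_index <- z
      detections[[z]] <- inh
    }  # else leave NULL; leading slices may have no detection
  }
  if (all(vapply(detections, is.null, logical(1)))) {
    msg <- "no reliable vertebra detection in volume"
    if (cfg$missing_vertebra == "error")
      stop(paste("processing error:", msg), call. = FALSE)
    warning(msg, call. = FALSE)
    empty <- binary_volume(array(0L, d), win$spacing)
    return(rib_mask(empty, detections,
                    removed = list(note = msg,
                                   stage_foreground = c(binarized = sum(bin$voxels == 255L),
                                                        final = 0L))))
  }

  fg_bin <- sum(bin$voxels == 255L)
  erased <- bin$voxels
  erase_log <- vector("list", d[3])
  band_limit <- d[1] - cfg$bed_band
  for (z in seq_len(d[3])) {
    if (is.null(detections[[z]])) next
    sl <- erased[, , z]
    fg_rows <- which(rowSums(sl[seq_len(band_limit), , drop = FALSE] == 255L) > 0)
    if (length(fg_rows) == 0L) next
    centroid_y <- (min(fg_rows) + max(fg_rows)) / 2
    er <- erase_vertebra_sternum(sl, detections[[z]], centroid_y,
                                 margin = cfg$erase_margin,
                                 sternum_scale = cfg$sternum_scale)
    erased[, , z] <- er$slice
    erase_log[[z]] <- list(vertebra_box = er$vertebra_box,
                           sternum_box = er$sternum_box)
  }
  erased <- binary_volume(erased, win$spacing)
  fg_erased <- sum(erased$voxels == 255L)

  cleaned <- remove_bed_and_noise(erased, min_size = cfg$min_size,
                                  opening_radius = cfg$opening_radius,
                                  bed_band = cfg$bed_band)
  fg_cleaned <- sum(cleaned$voxels == 255L)

  mask <- filter_nonrib_objects(cleaned, detections,
                                contact_margin = cfg$contact_margin)
  mask$removed$erase_boxes <- erase_log
  mask$removed$stage_foreground <- c(binarized = fg_bin, erased = fg_erased,
                                     cleaned = fg_cleaned,
                                     final = sum(mask$volume$voxels == 255L))
  mask
}

#' Read a template library from a directory of PNG files
#'
#' Loads every `.png` in the directory (ordered by filename) as an 8-bit
#' grayscale patch.
#'
#' @param dir directory of PNG files.
#' @return A [template_set()] with ids the file names.
#' @export
read_template_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("parameter error: no PNG templates in '%s'", dir), call. = FALSE)
  templates <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  template_set(templates, ids = sub("\\.png$", "", basename(files)))
}

#' Write a template library as PNG files
#'
#' @param templates a [template_set()].
#' @param dir output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_template_set <- function(templates, dir) {
  stopifnot(inherits(templates, "template_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(templates$templates), function(i) {
    p <- file.path(dir, paste0(templates$ids[i], ".png"))
    png::writePNG(templates$templates[[i]] / 255, p)
    p
  }, character(1))
  invisible(paths)
}
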