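# Synthetic axial thorax phantom with voxel-level ground truth.
#
# The phantom emulates a windowed chest CT stack for exercising the mask
# and labeling pipeline: 12 bilateral rib arcs attached posteriorly to a
# vertebral column, an anterior sternum, a scanner bed strip, a soft-tissue
# body ellipse, optional distractor bones, and configurable
# missing-12th-rib / fused-pair variants.  Geometric realism is bounded on
# purpose: the target is the algorithms' contracts, not photorealism.
#
# Construction guarantees the properties the labeler exploits:
#   * rib pairs are built superior -> inferior, so first-appearance order
#     equals anatomical ordinal order;
#   * every rib's most posterior voxels are face-adjacent to the vertebral
#     column on the rib's first slice;
#   * every structure is a dilation by the 3x3 brush (or a composition of
#     such dilations), hence invariant under the default morphological
#     opening;
#   * rib pairs occupy disjoint slice blocks, so no unintended rib-rib
#     contact can arise (the fused variant adds an explicit bridge).

#' Specify a synthetic thorax phantom
#'
#' Returns a validated parametric description of the phantom.  Defaults
#' are a full-complement, noise-free 512 x 512 x 56 stack at the
#' cohort-unified 0.798 mm in-plane spacing with a scanner bed and one
#' clavicle-like distractor.
#'
#' @param ny,nx,nz volume dimensions (rows, columns, slices).
#' @param spacing voxel size in mm, `c(z, y, x)`.
#' @param n_pairs number of rib pairs (default 12).
#' @param z_start first slice of rib pair 1.
#' @param span slices spanned by each rib.
#' @param gap slice offset between consecutive pairs' first slices
#'   (must be >= `span` so pairs stay slice-disjoint).
#' @param include_bed include the scanner bed strip.
#' @param include_vertebra include the vertebral column (disabling it
#'   voids the attachment invariant; used for degenerate-input tests).
#' @param distractors character subset of `c("clavicle", "scapula")`:
#'   bones detached from the vertebral column that a correct pipeline must
#'   exclude.
#' @param missing_rib `NULL`, or `list(side = "left"|"right", ordinal = k)`
#'   to omit one rib (emulates the absent/tiny 12th rib).
#' @param fused_pair `NULL`, or an ordinal `i` to bridge pairs `i` and
#'   `i + 1` into one connected bone on both sides (emulates adjacent true
#'   ribs converging near the sternum).
#' @param noise_sd additive Gaussian HU noise (default 0; the noise-free
#'   phantom is the reference condition).
#' @param bone_hu,soft_hu,air_hu,bed_hu intensity levels in HU.
#' @param seed integer seed controlling the (only) stochastic element,
#'   the additive noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ny = 512L, nx = 512L, nz = 56L,
                         spacing = c(z = 3, y = 0.798, x = 0.798),
                         n_pairs = 12L, z_start = 5L, span = 4L, gap = 4L,
                         include_bed = TRUE, include_vertebra = TRUE,
                         distractors = "clavicle",
                         missing_rib = NULL, fused_pair = NULL,
                         noise_sd = 0, bone_hu = 700, soft_hu = 40,
                         air_hu = -1000, bed_hu = 250, seed = 1L) {
  ny <- as.integer(ny); nx <- as.integer(nx); nz <- as.integer(nz)
  n_pairs <- as.integer(n_pairs)
  if (ny < 64L || nx < 64L) stop("spec error: in-plane dimensions must be at least 64", call. = FALSE)
  if (n_pairs < 1L) stop("spec error: n_pairs must be >= 1", call. = FALSE)
  if (gap < span) stop("spec error: gap < span would force rib-rib contact between pairs", call. = FALSE)
  if (z_start + (n_pairs - 1L) * gap + span - 1L > nz)
    stop("spec error: nz too small for the requested rib pairs", call. = FALSE)
  if (!is.null(missing_rib)) {
    if (!is.list(missing_rib) || !missing_rib$side %in% c("left", "right") ||
        missing_rib$ordinal < 1L || missing_rib$ordinal > n_pairs)
      stop("spec error: missing_rib must be list(side, ordinal)", call. = FALSE)
  }
  if (!is.null(fused_pair)) {
    fused_pair <- as.integer(fused_pair)
    if (fused_pair < 1L || fused_pair >= n_pairs)
      stop("spec error: fused_pair must name an ordinal with a successor", call. = FALSE)
  }
  if (!all(distractors %in% c("clavicle", "scapula")))
    stop("spec error: unknown distractor", call. = FALSE)
  cy <- ny / 2; cx <- nx / 2
  geom <- list(
    cy = cy, cx = cx,
    ry = round(0.293 * ny),            # rib arc radius, rows
    rx = round(0.361 * nx),            # rib arc radius, columns
    wv = max(3L, round(0.039 * nx)),   # vertebra half-width
    hv = max(4L, round(0.098 * ny)),   # vertebra height
    hs = max(3L, round(0.039 * ny)),   # sternum height
    ws = max(2L, round(0.023 * nx)),   # sternum half-width
    win = 0.9,                         # angular window per rib slice (rad)
    step = 0.45,                       # angular advance per slice (rad)
    taper = 0.03,                      # in-plane radial taper along the arc
    theta_max_true = 2.6,              # angular extent, true/false ribs
    theta_max_floating = 1.9           # angular extent, ribs 11-12
  )
  geom$theta_s <- asin(0.55 * geom$wv / geom$rx)  # arc start: head columns inside vertebra width
  structure(list(ny = ny, nx = nx, nz = nz,
                 spacing = c(z = unname(spacing[1]), y = unname(spacing[2]),
                             x = unname(spacing[3])),
                 n_pairs = n_pairs, z_start = as.integer(z_start),
                 span = as.integer(span), gap = as.integer(gap),
                 include_bed = isTRUE(include_bed),
                 include_vertebra = isTRUE(include_vertebra),
                 distractors = distractors,
                 missing_rib = missing_rib, fused_pair = fused_pair,
                 noise_sd = noise_sd, bone_hu = bone_hu, soft_hu = soft_hu,
                 air_hu = air_hu, bed_hu = bed_hu,
                 seed = as.integer(seed), geom = geom),
            class = "phantom_spec")
}

# dilate a pixel coordinate set by a (2r+1)x(2r+1) square, clipped
dilate_pixels <- function(yx, r, ny, nx) {
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    cbind(yx[, 1] + offs$dy[i], yx[, 2] + offs$dx[i])))
  out <- out[out[, 1] >= 1 & out[, 1] <= ny & out[, 2] >= 1 & out[, 2] <= nx, , drop = FALSE]
  unique(out)
}

# rasterize one rib arc segment (one side, one slice): returns (y, x) pixels
rib_segment_pixels <- function(spec, side, theta0, theta1) {
  g <- spec$geom
  if (theta1 <= theta0 + 0.02) return(NULL)
  th <- seq(theta0, theta1, by = 0.002)
  f <- 1 - g$taper * (th - g$theta_s)
  sgn <- if (side == "left") 1 else -1
  yx <- unique(cbind(round(g$cy + g$ry * f * cos(th)),
                     round(g$cx + sgn * g$rx * f * sin(th))))
  dilate_pixels(yx, 1L, spec$ny, spec$nx)
}

rib_theta_max <- function(spec, ordinal) {
  if (ordinal >= 11L) spec$geom$theta_max_floating else spec$geom$theta_max_true
}

# inclusive boxes of the fixed structures
phantom_boxes <- function(spec) {
  g <- spec$geom
  vy0 <- as.integer(round(g$cy + g$ry) + 2L)
  list(vertebra = c(vy0, vy0 + g$hv - 1L,
                    as.integer(round(g$cx - g$wv)), as.integer(round(g$cx + g$wv))),
       sternum = c(as.integer(round(g$cy - g$ry)),
                   as.integer(round(g$cy - g$ry)) + g$hs - 1L,
                   as.integer(round(g$cx - g$ws)), as.integer(round(g$cx + g$ws))),
       bed = c(spec$ny - 9L, spec$ny - 4L, 1L, spec$nx))
}

fill_box <- function(arr, box, z, value) {
  arr[box[1]:box[2], box[3]:box[4], z] <- value
  arr
}

#' Generate a phantom volume with ground truth
#'
#' Rasterizes the phantom described by a [phantom_spec()] into a CT volume
#' in HU plus voxel-level ground truth.  Deterministic given the spec's
#' seed; the generator validates its own output (pairwise-disjoint
#' structures, expected number of six-connected rib components, rib
#' attachment to the vertebral column) and raises a spec error on any
#' violation.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `rib_phantom`: list with `volume` (a
#'   [ct_volume()]), `truth` and `spec`.  `truth` contains `rib_labels`
#'   (integer array; left rib i coded i, right rib i coded `n_pairs + i`),
#'   `rib_table` (label/ordinal/side), `structures` (integer array),
#'   `structure_names`, and `n_components`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ny <- spec$ny; nx <- spec$nx; nz <- spec$nz
  boxes <- phantom_boxes(spec)
  structures <- array(0L, c(ny, nx, nz))
  struct_names <- character(0)
  code <- 0L
  add_struct <- function(name) {
    code <<- code + 1L
    struct_names[code] <<- name
    code
  }
  if (spec$include_vertebra) {
    vcode <- add_struct("vertebra")
    structures <- fill_box(structures, boxes$vertebra, seq_len(nz), vcode)
  }
  scode <- add_struct("sternum")
  structures <- fill_box(structures, boxes$sternum, seq_len(nz), scode)
  if (spec$include_bed) {
    bcode <- add_struct("bed")
    structures <- fill_box(structures, boxes$bed, seq_len(nz), bcode)
  }
  for (dname in spec$distractors) {
    dcode <- add_struct(dname)
    dpx <- distractor_pixels(spec, dname)
    for (z in dpx$slices) {
      idx <- cbind(dpx$pixels, z)
      if (any(structures[idx] != 0L))
        stop("spec error: distractor overlaps another structure", call. = FALSE)
      structures[idx] <- dcode
    }
  }

  # ribs, superior -> inferior so ordinal = first-appearance order
  g <- spec$geom
  rib_labels <- array(0L, c(ny, nx, nz))
  rib_rows <- list()
  for (i in seq_len(spec$n_pairs)) {
    z0 <- spec$z_start + (i - 1L) * spec$gap
    tmax <- rib_theta_max(spec, i)
    for (side in c("left", "right")) {
      if (!is.null(spec$missing_rib) && spec$missing_rib$side == side &&
          spec$missing_rib$ordinal == i) next
      lab <- if (side == "left") i else spec$n_pairs + i
      rib_rows[[length(rib_rows) + 1L]] <-
        data.frame(label = lab, ordinal = i, side = side)
      for (k in seq_len(spec$span) - 1L) {
        z <- z0 + k
        if (z > nz) break
        a <- g$theta_s + k * g$step
        b <- min(a + g$win, tmax)
        # fused variant: on the pair's last slice, extend the arc back to
        # the start angle so it meets the next pair's first-slice segment
        if (!is.null(spec$fused_pair) && i == spec$fused_pair &&
            k == spec$span - 1L) a <- g$theta_s
        px <- rib_segment_pixels(spec, side, a, b)
        if (is.null(px)) next
        idx <- cbind(px, z)
        clash <- structures[idx] != 0L | (rib_labels[idx] != 0L & rib_labels[idx] != lab)
        if (any(clash))
          stop("spec error: rib geometry collides with another structure", call. = FALSE)
        rib_labels[idx] <- lab
      }
    }
  }
  rib_table <- do.call(rbind, rib_rows)

  # validation: component count and vertebral attachment
  comps <- label_components_3d(rib_labels > 0L)
  expected <- expected_rib_components(spec)
  if (length(comps$clusters) != expected)
    stop(sprintf("spec error: phantom produced %d rib components, expected %d",
                 length(comps$clusters), expected), call. = FALSE)
  if (spec$include_vertebra) {
    vb <- boxes$vertebra
    for (r in seq_len(nrow(rib_table))) {
      i <- rib_table$ordinal[r]
      if (!is.null(spec$fused_pair) && i == spec$fused_pair + 1L) next  # reachable via bridge
      z0 <- spec$z_start + (i - 1L) * spec$gap
      sl <- rib_labels[, , z0] == rib_table$label[r]
      w <- which(sl, arr.ind = TRUE)
      adj <- any(w[, 1] >= vb[1] - 1L & w[, 1] <= vb[2] + 1L &
                 w[, 2] >= vb[3] & w[, 2] <= vb[4])
      if (!adj)
        stop("spec error: rib not attached to the vertebral column", call. = FALSE)
    }
  }

  # assemble HU volume
  vox <- array(spec$air_hu, c(ny, nx, nz))
  body <- body_ellipse_mask(spec)
  vox[rep(body, nz)] <- spec$soft_hu
  bone <- structures > 0L
  vox[bone] <- spec$bone_hu
  if (spec$include_bed) vox[structures == which(struct_names == "bed")] <- spec$bed_hu
  vox[rib_labels > 0L] <- spec$bone_hu
  if (spec$noise_sd > 0) {
    vox <- vox + with_local_seed(spec$seed, stats::rnorm(length(vox), 0, spec$noise_sd))
  }
  vox <- array(as.integer(round(vox)), c(ny, nx, nz))

  structure(list(volume = ct_volume(vox, spec$spacing),
                 truth = list(rib_labels = rib_labels,
                              rib_table = rib_table,
                              structures = structures,
                              structure_names = struct_names,
                              n_components = length(comps$clusters)),
                 spec = spec),
            class = "rib_phantom")
}

expected_rib_components <- function(spec) {
  n <- 0L
  for (side in c("left", "right")) {
    present <- seq_len(spec$n_pairs)
    if (!is.null(spec$missing_rib) && spec$missing_rib$side == side)
      present <- setdiff(present, spec$missing_rib$ordinal)
    k <- length(present)
    if (!is.null(spec$fused_pair) &&
        all(c(spec$fused_pair, spec$fused_pair + 1L) %in% present))
      k <- k - 1L
    n <- n + k
  }
  n
}

body_ellipse_mask <- function(spec) {
  g <- spec$geom
  by <- g$ry + g$hv + 6; bx <- g$rx + 10
  yy <- matrix(seq_len(spec$ny), spec$ny, spec$nx)
  xx <- matrix(seq_len(spec$nx), spec$ny, spec$nx, byrow = TRUE)
  ((yy - g$cy) / by)^2 + ((xx - g$cx) / bx)^2 <= 1
}

distractor_pixels <- function(spec, name) {
  ny <- spec$ny; nx <- spec$nx
  if (name == "clavicle") {
    # elongated bone on the patient-left (image-right) side, superior slices
    n <- 80L
    t <- seq(0, 1, length.out = n)
    yx <- unique(cbind(round(0.23 * ny + t * 0.04 * ny),
                       round(0.70 * nx + t * 0.14 * nx)))
    list(pixels = dilate_pixels(dilate_pixels(yx, 1L, ny, nx), 1L, ny, nx),
         slices = seq_len(min(6L, spec$nz)))
  } else {  # scapula-like blob, patient-right posterior
    cyd <- 0.74 * ny; cxd <- 0.18 * nx
    th <- seq(0, 2 * pi, length.out = 200)
    yx <- unique(cbind(round(cyd + 0.022 * ny * cos(th)),
                       round(cxd + 0.014 * nx * sin(th))))
    # fill interior by scanning rows
    filled <- do.call(rbind, lapply(split(yx[, 2], yx[, 1]), range))
    rows <- as.integer(rownames(filled))
    yx <- do.call(rbind, lapply(seq_along(rows), function(i)
      cbind(rows[i], filled[i, 1]:filled[i, 2])))
    list(pixels = dilate_pixels(yx, 1L, ny, nx),
         slices = seq(8L, min(20L, spec$nz)))
  }
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a vertebra template library from a phantom
#'
#' Crops windowed-and-binarized vertebra patches from the phantom at
#' varied slices, emulating a library of template images.  Each patch
#' strictly contains the vertebra cross-section (border widths cycle so
#' patch sizes vary); crop slices are chosen so the patch contains no
#' non-vertebral bone.
#'
#' @param phantom a `rib_phantom` from [generate_phantom()].
#' @param n_templates number of templates (default 15).
#' @param border integer vector of background border widths to cycle
#'   through.
#' @return A [template_set()].
#' @export
generate_template_set <- function(phantom, n_templates = 15L, border = 3:6) {
  stopifnot(inherits(phantom, "rib_phantom"))
  spec <- phantom$spec
  if (!spec$include_vertebra)
    stop("parameter error: phantom contains no vertebral column", call. = FALSE)
  if (n_templates > spec$nz)
    stop("parameter error: n_templates exceeds slice count", call. = FALSE)
  bmax <- max(border)
  vb <- phantom_boxes(spec)$vertebra
  crop_max <- clip_box(expand_box(vb, bmax), spec$ny, spec$nx)
  bin <- binarize(apply_window(phantom$volume))
  # clean slices: the maximal crop contains only vertebral foreground
  vcode <- which(phantom$truth$structure_names == "vertebra")
  clean <- vapply(seq_len(spec$nz), function(z) {
    sub <- crop_max[1]:crop_max[2]
    subx <- crop_max[3]:crop_max[4]
    fg <- bin$voxels[sub, subx, z] == 255L
    st <- phantom$truth$structures[sub, subx, z]
    rb <- phantom$truth$rib_labels[sub, subx, z]
    !any(fg & !(st == vcode)) && !any(rb > 0L)
  }, logical(1))
  clean <- which(clean)
  if (length(clean) < n_templates)
    stop("parameter error: not enough clean slices for the requested templates", call. = FALSE)
  pick <- clean[round(seq(1, length(clean), length.out = n_templates))]
  templates <- lapply(seq_len(n_templates), function(i) {
    b <- border[(i - 1L) %% length(border) + 1L]
    cb <- clip_box(expand_box(vb, b), spec$ny, spec$nx)
    bin$voxels[cb[1]:cb[2], cb[3]:cb[4], pick[i]]
  })
  template_set(templates)
}

#' @export
print.rib_phantom <- function(x, ...) {
  cat(sprintf("<rib_phantom> %d x %d x %d, %d rib components, structures: %s\n",
              x$spec$ny, x$spec$nx, x$spec$nz, x$truth$n_components,
              paste(x$truth$structure_names, collapse = ", ")))
  invisible(x)
}
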