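# Region growing: 2D four-connected and 3D six-connected flood fill.
# These primitives are the heart of the labeling method, so they are
# implemented here rather than delegated; connected-component utilities in
# other packages serve only as independent cross-checks in the tests.
#
# Both engines grow a seed by breadth-first frontier expansion over linear
# indices, one face-neighbour direction at a time, which keeps the inner
# loop fully vectorized.

# Grow the 4-connected component of `fg` (logical matrix) containing the
# linear-index seed set.  Returns linear indices of the component.
grow2d_engine <- function(fg, seed_lin) {
  ny <- nrow(fg); nx <- ncol(fg)
  member <- logical(length(fg))
  member[seed_lin] <- TRUE
  frontier <- seed_lin
  while (length(frontier)) {
    y <- (frontier - 1L) %% ny + 1L
    nxt <- integer(0)
    for (dir in 1:4) {
      cand <- switch(dir,
                     frontier[y > 1L] - 1L,        # up
                     frontier[y < ny] + 1L,        # down
                     frontier[frontier > ny] - ny, # left  (smaller x)
                     frontier[frontier <= (nx - 1L) * ny] + ny)  # right
      cand <- cand[fg[cand] & !member[cand]]
      if (length(cand)) {
        cand <- unique(cand)
        member[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- nxt
  }
  which(member)
}

# Grow the 6-connected component of `fg` (logical 3D array) containing the
# seed linear indices; `member` may carry already-visited voxels to skip.
grow3d_engine <- function(fg, seed_lin, member = NULL) {
  d <- dim(fg); ny <- d[1]; nx <- d[2]; nz <- d[3]
  plane <- ny * nx
  if (is.null(member)) member <- logical(length(fg))
  member[seed_lin] <- TRUE
  frontier <- seed_lin
  out <- frontier
  while (length(frontier)) {
    rem <- (frontier - 1L) %% plane
    y <- rem %% ny + 1L
    x <- rem %/% ny + 1L
    z <- (frontier - 1L) %/% plane + 1L
    nxt <- integer(0)
    for (dir in 1:6) {
      cand <- switch(dir,
                     frontier[y > 1L] - 1L,
                     frontier[y < ny] + 1L,
                     frontier[x > 1L] - ny,
                     frontier[x < nx] + ny,
                     frontier[z > 1L] - plane,
                     frontier[z < nz] + plane)
      cand <- cand[fg[cand] & !member[cand]]
      if (length(cand)) {
        cand <- unique(cand)
        member[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    out <- c(out, nxt)
    frontier <- nxt
  }
  list(voxels = out, member = member)
}

lin_to_zyx <- function(lin, d) {
  plane <- d[1] * d[2]
  rem <- (lin - 1L) %% plane
  cbind(z = (lin - 1L) %/% plane + 1L,
        y = rem %% d[1] + 1L,
        x = rem %/% d[1] + 1L)
}

zyx_to_lin <- function(z, y, x, d) {
  as.integer(y + (x - 1L) * d[1] + (z - 1L) * d[1] * d[2])
}

# scan order used throughout: slices first, then rows, then columns
scan_order <- function(lin, d) {
  co <- lin_to_zyx(lin, d)
  lin[order(co[, "z"], co[, "y"], co[, "x"])]
}

make_cluster <- function(id, lin, d) {
  lin <- scan_order(lin, d)
  co <- lin_to_zyx(lin, d)
  structure(list(id = id,
                 lin = lin,
                 size = length(lin),
                 first_slice = as.integer(co[1L, "z"]),
                 seed = co[1L, ],
                 centroid = c(z = mean(co[, "z"]), y = mean(co[, "y"]),
                              x = mean(co[, "x"])),
                 side = NA_character_,
                 pair_ordinal = NA_integer_),
            class = "cluster3d")
}

#' Grow one 3D six-connected cluster from a seed
#'
#' Starting at a foreground voxel, repeatedly includes every
#' face-adjacent (x, y, z axis) foreground neighbour until no voxel can be
#' added, yielding the maximal six-connected component containing the
#' seed.  Membership is deterministic and independent of traversal order.
#'
#' @param vol a [binary_volume()] or [rib_mask()].
#' @param seed integer `c(z, y, x)` voxel coordinates; must be foreground.
#' @param visited optional logical array of already-visited voxels; the
#'   grown cluster is marked into it and the updated array is attached as
#'   attribute `"visited"`.
#' @return A `cluster3d` object: voxel coordinates, size, first
#'   (most superior) slice, seed in scan order, centroid.
#' @export
grow_3d <- function(vol, seed, visited = NULL) {
  if (inherits(vol, "rib_mask")) vol <- vol$volume
  stopifnot(inherits(vol, "binary_volume"))
  d <- dim(vol$voxels)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d[c(3, 1, 2)]))
    stop("parameter error: seed (z, y, x) out of bounds", call. = FALSE)
  lin <- zyx_to_lin(seed[1], seed[2], seed[3], d)
  if (vol$voxels[lin] != 255L)
    stop("parameter error: seed is not a foreground voxel", call. = FALSE)
  if (!is.null(visited) && visited[lin])
    stop("parameter error: seed already visited", call. = FALSE)
  g <- grow3d_engine(vol$voxels == 255L, lin, visited)
  cl <- make_cluster(1L, g$voxels, d)
  attr(cl, "visited") <- g$member
  cl
}

#' @export
print.cluster3d <- function(x, ...) {
  cat(sprintf("<cluster3d> id %d: %d voxels, first slice %d, centroid (z %.1f, y %.1f, x %.1f)%s\n",
              x$id, x$size, x$first_slice,
              x$centroid["z"], x$centroid["y"], x$centroid["x"],
              if (!is.na(x$side)) paste0(", side ", x$side) else ""))
  invisible(x)
}

# Label all 6-connected components, seeding in scan order (slice, row,
# column).  Returns list(labels = integer array, clusters = list).
label_components_3d <- function(fgarray) {
  d <- dim(fgarray)
  fg <- fgarray
  labels <- array(0L, d)
  idx <- scan_order(which(fg), d)
  member <- logical(length(fg))
  clusters <- list()
  id <- 0L
  for (s in idx) {
    if (member[s]) next
    id <- id + 1L
    g <- grow3d_engine(fg, s, member)
    member <- g$member
    labels[g$voxels] <- id
    clusters[[id]] <- make_cluster(id, g$voxels, d)
  }
  list(labels = labels, clusters = clusters)
}

# Label all 4-connected components of a slice, seeding in raster order.
label_components_2d <- function(fgmat) {
  ny <- nrow(fgmat)
  idx <- which(fgmat)
  y <- (idx - 1L) %% ny + 1L
  x <- (idx - 1L) %/% ny + 1L
  idx <- idx[order(y, x)]  # raster: row by row, left to right
  member <- logical(length(fgmat))
  regions <- list()
  id <- 0L
  for (s in idx) {
    if (member[s]) next
    id <- id + 1L
    lin <- grow2d_engine(fgmat, s)
    member[lin] <- TRUE
    regions[[id]] <- lin
  }
  regions
}

#' Extract 2D four-connected objects from a binary slice
#'
#' Scans the slice in raster order (row by row from the top-left pixel);
#' each unvisited foreground pixel seeds a four-connected region grown to
#' completion.  Regions are returned in seed raster order.
#'
#' @param slice integer matrix over \{0, 255\}.
#' @return List of `region2d` objects with elements `pixels` (n x 2
#'   matrix of (y, x)), `seed`, `size`.
#' @export
extract_slice_objects <- function(slice) {
  stopifnot(is.matrix(slice))
  regions <- label_components_2d(slice == 255L)
  ny <- nrow(slice)
  lapply(seq_along(regions), function(i) {
    lin <- regions[[i]]
    y <- (lin - 1L) %% ny + 1L
    x <- (lin - 1L) %/% ny + 1L
    o <- order(y, x)
    structure(list(pixels = cbind(y = y[o], x = x[o]),
                   seed = c(y = y[o][1], x = x[o][1]),
                   size = length(lin)),
              class = "region2d")
  })
}
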