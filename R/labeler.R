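# 3D six-connected region growing turns a ribs-only mask into ordinal rib
# labels: clusters are discovered from the top slice in scan order, sided
# about the vertebral midline, paired bilaterally into rib pairs 1..12,
# and the final label volume is re-coded so left rib i carries label i and
# right rib i carries label P + i for P pairs.

#' Labeler configuration
#'
#' @param min_cluster_size clusters below this voxel count are dropped as
#'   noise (default 30; set 0 to keep everything).
#' @param max_pairs maximum number of rib pairs annotated (default 12).
#' @return A list of class `labeler_config`.
#' @export
labeler_config <- function(min_cluster_size = 30L, max_pairs = 12L) {
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 max_pairs = as.integer(max_pairs)),
            class = "labeler_config")
}

#' Label all 3D six-connected clusters in a rib mask
#'
#' Scans slices from the top in raster order; every unvisited foreground
#' voxel seeds a six-connected region grown to completion.  Clusters
#' smaller than `min_cluster_size` are dropped; survivors receive ids
#' 1, 2, ... in discovery order (first slice ascending, then raster order
#' of the seed).
#'
#' @param mask a [rib_mask()] or [binary_volume()].
#' @param min_cluster_size minimum cluster size in voxels.
#' @return List: `labels` (a [label_volume()]) and `clusters` (list of
#'   `cluster3d`).
#' @export
label_clusters <- function(mask, min_cluster_size = 30L) {
  vol <- if (inherits(mask, "rib_mask")) mask$volume else mask
  stopifnot(inherits(vol, "binary_volume"))
  d <- dim(vol$voxels)
  comps <- label_components_3d(vol$voxels == 255L)
  keep <- vapply(comps$clusters, function(cl) cl$size >= min_cluster_size, logical(1))
  clusters <- comps$clusters[keep]
  labels <- array(0L, d)
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- i
    labels[clusters[[i]]$lin] <- i
  }
  list(labels = label_volume(labels, vol$spacing), clusters = clusters)
}

#' Assign a body side to a cluster
#'
#' Under the fixed radiological display convention the patient's left is
#' at image right, so a centroid column beyond the midline means a left
#' rib; ties go right.
#'
#' @param cluster a `cluster3d`.
#' @param midline_x midline column; use the mean vertebra-box center
#'   column when detections are available, else the volume center column.
#' @return `"left"` or `"right"`.
#' @export
assign_side <- function(cluster, midline_x) {
  if (cluster$centroid["x"] > midline_x) "left" else "right"
}

#' Pair sided clusters into bilateral rib pairs
#'
#' Within each side, clusters sorted by (first slice, seed raster order)
#' receive side-ordinals 1, 2, ...; pair ordinal i joins left-ordinal i
#' with right-ordinal i.  Pairing stops at the smaller side count;
#' surplus clusters are reported as unpaired with a warning, and ordinals
#' beyond `max_pairs` are flagged (a non-rib object has been labeled).
#'
#' @param clusters list of `cluster3d` with `side` assigned.
#' @param max_pairs ordinal cap (default 12).
#' @param case_id optional case identifier carried into the report.
#' @return An object of class `rib_label_report`: `pairs`
#'   (ordinal/left_cluster_id/right_cluster_id), `unpaired`, `warnings`,
#'   `flags`, `n_pairs`.
#' @export
pair_ribs <- function(clusters, max_pairs = 12L, case_id = NA_character_) {
  if (length(clusters) && any(vapply(clusters, function(cl) is.na(cl$side), logical(1))))
    stop("parameter error: clusters must have sides assigned", call. = FALSE)
  warnings <- character(0)
  flags <- character(0)
  ord_of <- function(side) {
    cls <- Filter(function(cl) cl$side == side, clusters)
    if (length(cls) == 0L) return(cls)
    key <- vapply(cls, function(cl) c(cl$first_slice, cl$seed["y"], cl$seed["x"]),
                  numeric(3))
    cls[order(key[1, ], key[2, ], key[3, ])]
  }
  left <- ord_of("left"); right <- ord_of("right")
  p_full <- min(length(left), length(right))
  p <- min(p_full, max_pairs)
  pairs <- if (p > 0L)
    data.frame(ordinal = seq_len(p),
               left_cluster_id = vapply(left[seq_len(p)], `[[`, integer(1), "id"),
               right_cluster_id = vapply(right[seq_len(p)], `[[`, integer(1), "id"))
  else data.frame(ordinal = integer(0), left_cluster_id = integer(0),
                  right_cluster_id = integer(0))
  unp <- list()
  add_unpaired <- function(cls, side, from) {
    for (j in seq_along(cls)) {
      if (j + from <= p) next
      unp[[length(unp) + 1L]] <<- data.frame(cluster_id = cls[[j + from]]$id,
                                             side = side, side_ordinal = j + from)
    }
  }
  if (length(left) > p) add_unpaired(left, "left", 0L)
  if (length(right) > p) add_unpaired(right, "right", 0L)
  unpaired <- if (length(unp)) do.call(rbind, unp)
  else data.frame(cluster_id = integer(0), side = character(0), side_ordinal = integer(0))
  unpaired <- unpaired[unpaired$side_ordinal > p, , drop = FALSE]
  if (length(left) != length(right))
    warnings <- c(warnings, sprintf("side asymmetry: %d left vs %d right clusters",
                                    length(left), length(right)))
  if (p_full > max_pairs) {
    warnings <- c(warnings, sprintf("more than %d pairs found (%d); non-rib object likely labeled",
                                    max_pairs, p_full))
    flags <- c(flags, "too_many_pairs")
  }
  structure(list(case_id = case_id, pairs = pairs, unpaired = unpaired,
                 annotations = data.frame(ordinal = integer(0), z = integer(0),
                                          y = integer(0), x = integer(0)),
                 warnings = warnings, flags = flags, n_pairs = p),
            class = "rib_label_report")
}

#' Label the rib sequence of a ribs-only mask
#'
#' Full sequence labeling: six-connected clustering, side assignment
#' about the vertebral midline, bilateral pairing, re-coding of the label
#' volume (left rib i -> i, right rib i -> P + i for P pairs), and
#' left-side display annotations placed at each left cluster's
#' lateral-most voxel on its first slice.
#'
#' @param mask a [rib_mask()] or [binary_volume()].
#' @param config a [labeler_config()].
#' @param case_id optional case identifier.
#' @return List: `labels` (re-coded [label_volume()]) and `report`
#'   (a `rib_label_report` with annotations filled in).
#' @export
label_sequence <- function(mask, config = labeler_config(), case_id = NA_character_) {
  vol <- if (inherits(mask, "rib_mask")) mask$volume else mask
  d <- dim(vol$voxels)
  lc <- label_clusters(mask, config$min_cluster_size)
  dets <- if (inherits(mask, "rib_mask")) Filter(Negate(is.null), mask$detections) else list()
  midline_x <- if (length(dets))
    mean(vapply(dets, function(dt) (dt$box[3] + dt$box[4]) / 2, numeric(1)))
  else (d[2] + 1) / 2
  clusters <- lapply(lc$clusters, function(cl) {
    cl$side <- assign_side(cl, midline_x)
    cl
  })
  report <- pair_ribs(clusters, config$max_pairs, case_id)
  p <- report$n_pairs
  labels <- array(0L, d)
  ann <- list()
  for (i in seq_len(p)) {
    lcl <- clusters[[report$pairs$left_cluster_id[i]]]
    rcl <- clusters[[report$pairs$right_cluster_id[i]]]
    labels[lcl$lin] <- i
    labels[rcl$lin] <- p + i
    co <- lin_to_zyx(lcl$lin, d)
    co <- co[co[, "z"] == lcl$first_slice, , drop = FALSE]
    at <- co[which.max(co[, "x"]), ]
    ann[[i]] <- data.frame(ordinal = i, z = at[["z"]], y = at[["y"]], x = at[["x"]])
  }
  for (i in seq_len(p)) {
    clusters[[report$pairs$left_cluster_id[i]]]$pair_ordinal <- i
    clusters[[report$pairs$right_cluster_id[i]]]$pair_ordinal <- i
  }
  if (length(ann)) report$annotations <- do.call(rbind, ann)
  report$midline_x <- midline_x
  list(labels = label_volume(labels, vol$spacing), report = report,
       clusters = clusters)
}

#' @export
print.rib_label_report <- function(x, ...) {
  cat(sprintf("<rib_label_report>%s %d rib pairs, %d unpaired cluster(s)\n",
              if (!is.na(x$case_id)) paste0(" case ", x$case_id, ":") else "",
              x$n_pairs, nrow(x$unpaired)))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
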