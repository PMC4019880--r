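# Per-region statistics of labeled volumes: centroids (voxel-mean), sizes,
# boundary-touch classification, and per-plane contours for visualization.

#' Region centroids of a labeled volume
#'
#' For each label k with voxel set Omega_k, the centroid is the coordinate
#' mean C_k = (sum x / |Omega_k|, sum y / |Omega_k|, sum z / |Omega_k|)
#' over the voxel indices in Omega_k (0-based voxel coordinates), mirrored
#' in micrometres as coordinate times per-axis spacing.
#'
#' @param vol a `labeled_volume`.
#' @param spacing voxel spacing in micrometres; defaults to the volume's.
#' @return a data frame with one row per label: `label`, voxel-coordinate
#'   centroid (`x_vox`, `y_vox`, `z_vox`), micrometre centroid (`x_um`,
#'   `y_um`, `z_um`), `n_voxels`, and `boundary` (1 if the region touches
#'   any stack face).
#' @export
region_centroids <- function(vol, spacing = attr(vol, "spacing")) {
  labs_arr <- unclass(vol)
  idx <- which(labs_arr > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(), x_vox = numeric(), y_vox = numeric(),
                      z_vox = numeric(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), n_voxels = integer(),
                      boundary = integer()))
  }
  labs <- labs_arr[idx]
  ai <- arrayInd(idx, dim(vol))
  # 0-based voxel coordinates: x = col - 1, y = row - 1, z = plane - 1
  co <- cbind(x = ai[, 2] - 1, y = ai[, 1] - 1, z = ai[, 3] - 1)
  sums <- rowsum(co, labs)
  cnt <- as.integer(rowsum(rep(1L, length(labs)), labs))
  lab_ids <- as.integer(rownames(sums))
  cent <- sums / cnt
  flags <- boundary_touch_flags(vol)
  data.frame(label = lab_ids,
             x_vox = cent[, "x"], y_vox = cent[, "y"], z_vox = cent[, "z"],
             x_um = cent[, "x"] * spacing["x"],
             y_um = cent[, "y"] * spacing["y"],
             z_um = cent[, "z"] * spacing["z"],
             n_voxels = cnt,
             boundary = as.integer(flags[lab_ids]),
             row.names = NULL)
}

#' Boundary-touch flags per label
#'
#' A region touches the boundary iff any of its voxels lies on one of the
#' six stack faces (first or last index of any axis). This mirrors the
#' ground-truth distinction between cells completely contained in the stack
#' and cells intersecting its boundary.
#'
#' @param vol a `labeled_volume`.
#' @return logical vector indexed by label.
#' @export
boundary_touch_flags <- function(vol) {
  n <- n_labels(vol)
  if (n == 0L) return(logical())
  a <- unclass(vol)
  d <- dim(a)
  face_labels <- c(a[1, , ], a[d[1], , ], a[, 1, ], a[, d[2], ],
                   a[, , 1], a[, , d[3]])
  flags <- logical(n)
  face_labels <- face_labels[face_labels > 0L]
  flags[unique(face_labels)] <- TRUE
  flags
}

#' Per-plane region contours
#'
#' For one XY plane, returns the contour voxels of every region present in
#' that plane: foreground voxels with at least one 4-neighbor (within the
#' plane; outside the image counts as background) carrying a different
#' label. Intended for visualization export only.
#'
#' @param vol a `labeled_volume`.
#' @param plane 1-based z index.
#' @return data frame `label, x_vox, y_vox, plane` of contour voxels
#'   (0-based voxel coordinates).
#' @export
plane_boundaries <- function(vol, plane) {
  d <- dim(vol)
  if (plane < 1L || plane > d[3]) stop("`plane` out of range")
  m <- unclass(vol)[, , plane]
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(0L, ny + 2L, nx + 2L)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  core <- pad[2:(ny + 1), 2:(nx + 1)]
  diff_any <- (pad[1:ny, 2:(nx + 1)] != core) |
    (pad[3:(ny + 2), 2:(nx + 1)] != core) |
    (pad[2:(ny + 1), 1:nx] != core) |
    (pad[2:(ny + 1), 3:(nx + 2)] != core)
  sel <- which(core > 0L & diff_any, arr.ind = TRUE)
  data.frame(label = core[core > 0L & diff_any],
             x_vox = sel[, 2] - 1L, y_vox = sel[, 1] - 1L,
             plane = rep(plane - 1L, nrow(sel)), row.names = NULL)
}

# Marker set at region centroids (used by the detector and the benchmark).
centroid_markers <- function(vol, spacing = attr(vol, "spacing")) {
  rc <- region_centroids(vol, spacing)
  marker_set(rc$label, rc$x_um, rc$y_um, rc$z_um,
             boundary = rc$boundary, n_voxels = rc$n_voxels,
             spacing = spacing)
}
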