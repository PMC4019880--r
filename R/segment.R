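# Baseline automated 3D detector: global intensity threshold, 3D connected
# components, size filter — the simplest cell-appearance model, retained
# deliberately so that its known failure modes (under-segmentation of
# touching cells, sensitivity to a single global threshold) are exercised.

#' Detector parameters
#'
#' @param threshold global intensity threshold in stack units (digital
#'   numbers for integer stacks, \[0, 1\] for real-valued ones). Voxels with
#'   intensity `>= threshold` are foreground (inclusive convention).
#' @param connectivity 6, 18 or 26 (default 26, the common choice for
#'   blob-like cells in 3D object counting).
#' @param min_voxels regions with fewer voxels than this are removed
#'   (strictly smaller; the boundary case is kept). 0 disables.
#' @param smoothing optional [smoothing_spec()] applied before thresholding.
#' @return a `detector_params` list.
#' @export
detector_params <- function(threshold, connectivity = 26L, min_voxels = 0L,
                            smoothing = NULL) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (min_voxels < 0L) stop("min_voxels must be >= 0")
  structure(list(threshold = threshold,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels),
                 smoothing = smoothing),
            class = "detector_params")
}

#' Threshold a stack into a binary mask
#'
#' Foreground iff intensity `>= level`.
#'
#' @param stack grayscale `image_stack` or 3D array.
#' @param level threshold in stack units.
#' @return logical 3D array with the stack's spacing attached.
#' @export
threshold_stack <- function(stack, level) {
  a <- unclass(stack)
  if (length(dim(a)) != 3L) stop("`stack` must be single-channel (3D)")
  m <- a >= level
  attr(m, "spacing") <- attr(stack, "spacing")
  m
}

#' 3D connected components of a binary mask
#'
#' Two foreground voxels share a label iff they are connected under the
#' chosen neighborhood. Labels are compacted positive integers assigned in
#' raster-scan order of each component's first voxel, so the labeling is
#' deterministic.
#'
#' @param mask logical 3D array (optionally with a `spacing` attribute).
#' @param connectivity 6, 18 or 26.
#' @param spacing voxel spacing for the result; defaults to the mask's.
#' @return a `labeled_volume`.
#' @export
connected_components_3d <- function(mask, connectivity = 26L,
                                    spacing = attr(mask, "spacing")) {
  if (length(dim(mask)) != 3L) stop("`mask` must be 3D")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  labs <- .cc3d_label(as.logical(mask), as.integer(dim(mask)),
                      as.integer(connectivity))
  labeled_volume(array(labs, dim(mask)), spacing = spacing,
                 connectivity = as.integer(connectivity))
}

#' Remove small regions from a labeled volume
#'
#' Regions with strictly fewer than `min_voxels` voxels are relabeled to
#' background; surviving labels are compacted (order preserved) and their
#' voxel sets are unchanged.
#'
#' @param vol a `labeled_volume`.
#' @param min_voxels minimum region size to keep.
#' @return a `labeled_volume`.
#' @export
size_filter <- function(vol, min_voxels) {
  if (min_voxels <= 0L) return(vol)
  sizes <- label_sizes(vol)
  if (!length(sizes)) return(vol)
  keep <- sizes >= min_voxels
  map <- integer(length(sizes))
  map[keep] <- seq_len(sum(keep))
  a <- unclass(vol)
  pos <- a > 0L
  a[pos] <- map[a[pos]]
  labeled_volume(a, spacing = attr(vol, "spacing"),
                 connectivity = attr(vol, "connectivity"))
}

#' Run the baseline detector on a stack
#'
#' Optional 3D Gaussian smoothing, global threshold, connected components,
#' size filter, then centroid extraction. One detection marker is emitted
#' per surviving region, at its voxel-mean centroid, with the region size
#' attached.
#'
#' @param stack grayscale `image_stack`.
#' @param params a [detector_params()].
#' @return list with `labels` (a `labeled_volume`) and `markers`
#'   (a `marker_set` of detections).
#' @export
detect_cells <- function(stack, params) {
  stopifnot(inherits(params, "detector_params"))
  s <- stack
  if (!is.null(params$smoothing)) s <- gaussian_smooth_3d(s, params$smoothing)
  mask <- threshold_stack(s, params$threshold)
  vol <- connected_components_3d(mask, params$connectivity,
                                 spacing = stack_spacing(stack))
  vol <- size_filter(vol, params$min_voxels)
  list(labels = vol, markers = centroid_markers(vol))
}

#' Physical volume of a size filter
#'
#' The micrometre-cube volume corresponding to a voxel-count size filter
#' under a profile's spacing: `min_voxels * sx * sy * sz`.
#'
#' @param min_voxels voxel count.
#' @param spacing voxel spacing (x, y, z) in micrometres, or an
#'   `acquisition_profile`.
#' @return volume in cubic micrometres.
#' @export
size_filter_volume_um3 <- function(min_voxels, spacing) {
  if (inherits(spacing, "acquisition_profile"))
    spacing <- c(spacing$lateral_spacing_x, spacing$lateral_spacing_y,
                 spacing$axial_spacing)
  min_voxels * prod(as.numeric(spacing))
}
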