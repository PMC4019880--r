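# Core containers shared by all pipeline stages.
#
# Array convention (global): a grayscale stack is a 3D numeric array with
# dim = c(ny, nx, nz); a multi-channel stack is 4D with dim = c(ny, nx, nz,
# n_channels). Voxel indices are 1-based in R but the physical coordinate
# convention is 0-based: the voxel at (row i, col j, plane k) sits at
# x = (j - 1) * spacing_x, y = (i - 1) * spacing_y, z = (k - 1) * spacing_z,
# all in micrometres. No half-voxel offset is applied.

#' Construct an image stack
#'
#' A 3D (grayscale) or 4D (multi-channel) voxel grid with anisotropic
#' physical spacing. Values are digital numbers in `[0, 2^depth - 1]` for
#' integer stacks, or real numbers (typically in \[0, 1\], e.g. a
#' chromaticity channel) when `depth = NA`.
#'
#' @param data numeric array, `c(ny, nx, nz)` or `c(ny, nx, nz, ch)`.
#' @param spacing numeric length-3, micrometres per voxel along x, y, z.
#' @param depth bit depth (8 or 16), or `NA` for real-valued stacks.
#' @param modality `"fluorescence"` or `"brightfield_rgb"`.
#' @param channels channel names for 4D stacks (e.g. `c("R","G","B")`).
#' @return an `image_stack` object (numeric array with attributes).
#' @export
image_stack <- function(data, spacing, depth = 8L,
                        modality = "fluorescence", channels = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (x, y, z) in micrometres")
  names(spacing) <- c("x", "y", "z")
  if (length(dim(data)) == 4L) {
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4]))
    if (length(channels) != dim(data)[4])
      stop("`channels` must name every channel")
  } else channels <- NULL
  structure(data,
            spacing = spacing, depth = depth, modality = modality,
            channels = channels, class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %s voxels (y,x,z%s), spacing %s um, depth %s\n",
              paste(d, collapse = " x "),
              if (length(d) == 4L) ",ch" else "",
              paste(signif(attr(x, "spacing"), 4), collapse = " x "),
              if (is.na(stack_depth(x))) "real" else stack_depth(x)))
  invisible(x)
}

stack_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("stack has no spacing attribute")
  sp
}

stack_depth <- function(x) {
  d <- attr(x, "depth")
  if (is.null(d)) NA_integer_ else d
}

is_rgb_stack <- function(x) {
  length(dim(x)) == 4L && dim(x)[4] == 3L &&
    identical(attr(x, "channels"), c("R", "G", "B"))
}

# Rebuild an image_stack around new voxel data, keeping geometry metadata.
restack <- function(data, template, depth = attr(template, "depth"),
                    modality = attr(template, "modality"), channels = NULL) {
  image_stack(data, spacing = stack_spacing(template), depth = depth,
              modality = modality, channels = channels)
}

#' Construct a marker set
#'
#' A set of point annotations (ground-truth cells or detections) in physical
#' micrometre coordinates. The `boundary` flag is 1 for cells whose support
#' intersects the stack boundary and 0 for cells completely contained in the
#' stack interior.
#'
#' @param id integer ids (unique).
#' @param x_um,y_um,z_um coordinates in micrometres.
#' @param boundary 0/1 flags (default all 0).
#' @param n_voxels optional region sizes for detection markers.
#' @param spacing optional declared voxel spacing of the coordinate frame;
#'   used to detect frame mismatches when matching.
#' @return a `marker_set` data frame.
#' @export
marker_set <- function(id = integer(), x_um = numeric(), y_um = numeric(),
                       z_um = numeric(), boundary = rep(0L, length(id)),
                       n_voxels = NULL, spacing = NULL) {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("marker ids must be unique")
  if (!all(boundary %in% c(0L, 1L)))
    stop("`boundary` flags must be 0 or 1")
  df <- data.frame(id = id, x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   z_um = as.numeric(z_um), boundary = as.integer(boundary))
  if (!is.null(n_voxels)) df$n_voxels <- as.integer(n_voxels)
  n <- nrow(df)
  if (length(unique(c(n, length(x_um), length(y_um), length(z_um)))) != 1L)
    stop("marker columns must have equal length")
  structure(df, spacing = spacing, class = c("marker_set", "data.frame"))
}

as_marker_set <- function(df, spacing = NULL) {
  marker_set(df$id, df$x_um, df$y_um, df$z_um,
             boundary = if (is.null(df$boundary)) rep(0L, nrow(df)) else df$boundary,
             n_voxels = df$n_voxels, spacing = spacing)
}

#' Construct a labeled volume
#'
#' An integer-labeled segmentation of a stack. Label 0 is background;
#' positive labels are consecutive after compaction. Per-label voxel counts
#' are stored in the `sizes` attribute.
#'
#' @param labels integer 3D array.
#' @param spacing voxel spacing in micrometres (x, y, z).
#' @param connectivity the neighborhood (6, 18 or 26) under which each label
#'   is connected, or `NA` when not applicable (e.g. synthetic truth).
#' @return a `labeled_volume` object.
#' @export
labeled_volume <- function(labels, spacing, connectivity = NA_integer_) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  spacing <- as.numeric(spacing)
  names(spacing) <- c("x", "y", "z")
  n_lab <- if (length(labels) && max(labels) > 0L) max(labels) else 0L
  sizes <- if (n_lab > 0L) tabulate(labels[labels > 0L], nbins = n_lab) else integer()
  structure(labels, spacing = spacing, sizes = sizes,
            connectivity = connectivity, class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels, %d regions\n",
              paste(dim(x), collapse = " x "), n_labels(x)))
  invisible(x)
}

#' Number of labeled regions in a volume
#' @param vol a `labeled_volume`.
#' @return integer count of positive labels.
#' @export
n_labels <- function(vol) length(attr(vol, "sizes"))

#' Per-label voxel counts
#' @param vol a `labeled_volume`.
#' @return integer vector, entry k is the size of region k.
#' @export
label_sizes <- function(vol) attr(vol, "sizes")
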