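# Color/intensity preprocessing: converts any supported stack into the
# single-channel bright-on-dark form the detector expects.

#' Smoothing specification for the 3D Gaussian filter
#'
#' Standard deviations are in voxel units, deliberately independent of the
#' optical resolution (the filter targets camera noise, not the PSF).
#'
#' @param sigma_x,sigma_y,sigma_z non-negative standard deviations in voxels.
#' @return a `smoothing_spec` list.
#' @export
smoothing_spec <- function(sigma_x = 2, sigma_y = 2, sigma_z = 1) {
  s <- c(x = sigma_x, y = sigma_y, z = sigma_z)
  if (any(!is.finite(s)) || any(s < 0)) stop("sigmas must be non-negative")
  structure(as.list(s), class = "smoothing_spec")
}

#' Invert the red channel of an RGB stack
#'
#' Brightfield DAB-stained cells are darker than the background in the red
#' channel; inversion makes them bright on dark, as the detector expects.
#' Output voxel value is `(2^depth - 1) - R`.
#'
#' @param stack an RGB `image_stack` with integer bit depth.
#' @return a grayscale `image_stack` of the same geometry and depth.
#' @export
invert_red_channel <- function(stack) {
  if (!is_rgb_stack(stack)) stop("`stack` must be an RGB image stack")
  d <- stack_depth(stack)
  if (is.na(d)) stop("RGB stack must have an integer bit depth")
  out <- (2^d - 1) - unclass(stack)[, , , 1L, drop = TRUE]
  restack(array(out, dim(stack)[1:3]), stack, modality = "fluorescence")
}

#' Red chromaticity channel (Lrg color-ratio space)
#'
#' Per-voxel `r = R / (R + G + B)`, computed independently for each voxel so
#' that only contrast, not resolution, is affected. DAB-brown cell regions
#' come out brighter than a neutral background (r > 1/3). Black voxels
#' (R + G + B = 0) are defined to have r = 0: in a brightfield context they
#' can only be background.
#'
#' @param stack an RGB `image_stack`.
#' @return a real-valued grayscale `image_stack` with values in \[0, 1\]
#'   (`depth = NA`); use [quantize_values()] to export at a bit depth.
#' @export
red_chromaticity <- function(stack) {
  if (!is_rgb_stack(stack)) stop("`stack` must be an RGB image stack")
  a <- unclass(stack)
  R <- a[, , , 1L, drop = TRUE]
  s <- R + a[, , , 2L, drop = TRUE] + a[, , , 3L, drop = TRUE]
  r <- ifelse(s > 0, R / s, 0)
  restack(array(r, dim(stack)[1:3]), stack, depth = NA_integer_,
          modality = "fluorescence")
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a single-channel stack with an anisotropic Gaussian kernel,
#' applied separably along x, y and z. Kernels are sampled Gaussians
#' normalized to unit mass, truncated at 4 sigma; boundaries use symmetric
#' (edge-including) reflection, which preserves total intensity mass for
#' interior structures.
#'
#' @param stack a grayscale `image_stack` or plain 3D array.
#' @param spec a [smoothing_spec()] (sigmas in voxels), or numeric length 3
#'   `(sigma_x, sigma_y, sigma_z)`.
#' @return a real-valued stack of the same geometry.
#' @export
gaussian_smooth_3d <- function(stack, spec) {
  if (inherits(spec, "smoothing_spec")) spec <- unlist(spec)
  spec <- as.numeric(spec)
  if (length(spec) != 3L) stop("`spec` must give sigma_x, sigma_y, sigma_z")
  if (any(spec < 0)) stop("sigmas must be non-negative")
  a <- unclass(stack)
  if (length(dim(a)) != 3L) stop("`stack` must be single-channel (3D)")
  # dim order is (y, x, z); spec order is (x, y, z)
  a <- conv_axis_gauss(a, spec[2], 1L)
  a <- conv_axis_gauss(a, spec[1], 2L)
  a <- conv_axis_gauss(a, spec[3], 3L)
  if (inherits(stack, "image_stack"))
    restack(a, stack, depth = attr(stack, "depth")) else a
}

# 1-D Gaussian convolution along one axis of a 3D array, symmetric padding.
conv_axis_gauss <- function(a, sigma, axis) {
  if (sigma == 0) return(a)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  n <- dm[1]
  m <- matrix(m, nrow = n)
  # symmetric reflection indices: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
  idx <- c(pmin(r:1, n), 1:n, pmax(n - 0:(r - 1), 1L))
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * p[j:(j + n - 1), , drop = FALSE]
  aperm(array(out, dm), order(perm))
}

#' Extract a named channel from a multi-channel stack
#'
#' Fluorescent channels are addressed by role label (as named when the stack
#' was merged); RGB channels by `"R"`, `"G"`, `"B"`.
#'
#' @param stack a 4D `image_stack`.
#' @param channel channel name.
#' @return a grayscale `image_stack` of the same geometry.
#' @export
extract_channel <- function(stack, channel) {
  ch <- attr(stack, "channels")
  if (is.null(ch)) stop("`stack` has no channels")
  i <- match(channel, ch)
  if (is.na(i)) stop(sprintf("unknown channel '%s' (have: %s)", channel,
                             paste(ch, collapse = ", ")))
  a <- unclass(stack)[, , , i, drop = TRUE]
  restack(array(a, dim(stack)[1:3]), stack, modality = "fluorescence")
}

#' Merge grayscale stacks into a multi-channel stack
#'
#' @param stacks list of grayscale `image_stack`s sharing geometry.
#' @param channels channel names.
#' @param modality stored modality label.
#' @return a 4D `image_stack`.
#' @export
merge_channels <- function(stacks, channels, modality = "fluorescence") {
  stopifnot(length(stacks) == length(channels), length(stacks) >= 1L)
  d <- dim(stacks[[1]])
  for (s in stacks) if (!identical(dim(s), d)) stop("geometry mismatch")
  a <- array(0, c(d, length(stacks)))
  for (i in seq_along(stacks)) a[, , , i] <- unclass(stacks[[i]])
  image_stack(a, spacing = stack_spacing(stacks[[1]]),
              depth = attr(stacks[[1]], "depth"), modality = modality,
              channels = channels)
}
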