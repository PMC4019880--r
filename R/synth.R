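# Synthetic 3D image stacks with exactly known ground truth, emulating the
# four acquisition conditions of the benchmark (widefield fluorescence,
# confocal, spinning-disc, and brightfield DAB) so every downstream stage
# is testable without the original image data.

#' Acquisition profile
#'
#' The per-dataset imaging geometry: anisotropic voxel spacing, stack
#' dimensions, modality, and which compartment the label targets.
#'
#' @param name label for reports.
#' @param lateral_spacing_x,lateral_spacing_y micrometres per voxel in XY.
#' @param axial_spacing micrometres between image planes.
#' @param width,height voxels per image plane (width = x = columns).
#' @param n_planes number of image planes.
#' @param modality `"fluorescence"` or `"brightfield_rgb"`.
#' @param label_target `"nucleus"` or `"cytoplasm"`.
#' @param reported_cells optional published ground-truth count (metadata).
#' @param min_voxels default detector size filter for this profile.
#' @param axial_tolerance default axial matching tolerance (micrometres).
#' @return an `acquisition_profile` list.
#' @export
acquisition_profile <- function(name, lateral_spacing_x, lateral_spacing_y,
                                axial_spacing, width, height, n_planes,
                                modality = c("fluorescence", "brightfield_rgb"),
                                label_target = c("nucleus", "cytoplasm"),
                                reported_cells = NA_integer_,
                                min_voxels = 1000L, axial_tolerance = 1.5) {
  modality <- match.arg(modality)
  label_target <- match.arg(label_target)
  if (any(c(lateral_spacing_x, lateral_spacing_y, axial_spacing) <= 0))
    stop("spacings must be positive")
  if (n_planes < 1L || width < 1L || height < 1L)
    stop("stack dimensions must be at least 1")
  structure(list(name = name,
                 lateral_spacing_x = lateral_spacing_x,
                 lateral_spacing_y = lateral_spacing_y,
                 axial_spacing = axial_spacing,
                 width = as.integer(width), height = as.integer(height),
                 n_planes = as.integer(n_planes),
                 modality = modality, label_target = label_target,
                 reported_cells = as.integer(reported_cells),
                 min_voxels = as.integer(min_voxels),
                 axial_tolerance = axial_tolerance),
            class = "acquisition_profile")
}

profile_spacing <- function(profile) {
  c(x = profile$lateral_spacing_x, y = profile$lateral_spacing_y,
    z = profile$axial_spacing)
}

profile_extent <- function(profile) {
  # physical extent of the voxel-center lattice, micrometres
  c(x = (profile$width - 1) * profile$lateral_spacing_x,
    y = (profile$height - 1) * profile$lateral_spacing_y,
    z = (profile$n_planes - 1) * profile$axial_spacing)
}

#' The four benchmark acquisition presets
#'
#' Geometry of the four 3D microscopic images of mouse brain used in the
#' published benchmark: "3A" widefield fluorescence DAPI (cerebral cortex),
#' "3B" confocal Sox2 (hippocampus), "3C" spinning-disc NeuN (cerebral
#' cortex, cytoplasmic label), "3D" brightfield DAB NeuN (striatum).
#' Default size filters follow the voxel-volume arithmetic of the published
#' filters (1000 voxels at the 0.102/0.075 um spacings, 25 voxels at the
#' 0.46 um spacing); the 2.0 um axial matching tolerance goes with the
#' low-numerical-aperture confocal profile.
#'
#' @return named list of four [acquisition_profile()]s.
#' @export
preset_profiles <- function() {
  list(
    "3A" = acquisition_profile("3A", 0.102134, 0.101507, 0.5, 1388, 1040, 45,
                               "fluorescence", "nucleus",
                               reported_cells = 154L, min_voxels = 1000L,
                               axial_tolerance = 1.5),
    "3B" = acquisition_profile("3B", 0.46056, 0.46056, 1.0, 512, 512, 51,
                               "fluorescence", "nucleus",
                               reported_cells = 246L, min_voxels = 25L,
                               axial_tolerance = 2.0),
    "3C" = acquisition_profile("3C", 0.102134, 0.101507, 0.5, 1344, 1024, 26,
                               "fluorescence", "cytoplasm",
                               reported_cells = 53L, min_voxels = 1000L,
                               axial_tolerance = 1.5),
    "3D" = acquisition_profile("3D", 0.075173, 0.074300, 0.5, 1600, 1200, 45,
                               "brightfield_rgb", "cytoplasm",
                               reported_cells = 58L, min_voxels = 1000L,
                               axial_tolerance = 1.5)
  )
}

#' Rescale a profile's stack dimensions
#'
#' Keeps spacing, modality and per-profile defaults while shrinking (or
#' growing) the voxel grid — used to run the benchmark at desk scale.
#'
#' @param profile an [acquisition_profile()].
#' @param width,height,n_planes replacement dimensions (NULL keeps current).
#' @return an `acquisition_profile`.
#' @export
scale_profile <- function(profile, width = NULL, height = NULL,
                          n_planes = NULL) {
  if (!is.null(width)) profile$width <- as.integer(width)
  if (!is.null(height)) profile$height <- as.integer(height)
  if (!is.null(n_planes)) profile$n_planes <- as.integer(n_planes)
  profile
}

#' Cell population specification
#'
#' @param n_cells number of cells to place.
#' @param radius_xy_range lateral semi-axis range in micrometres (default
#'   2–2.5 um: nuclei with 4–5 um XY diameter).
#' @param radius_z_range axial semi-axis range in micrometres.
#' @param clustering offspring dispersion (micrometres) of a Thomas-process
#'   placement; 0 gives uniform (hard-core) placement.
#' @param min_separation minimum center-to-center distance in micrometres.
#' @param intensity_range per-cell label intensity range, normalized \[0,1\].
#' @param allow_boundary_cut if `FALSE`, cells are constrained to lie
#'   entirely inside the stack.
#' @return a `cell_population` list.
#' @export
cell_population <- function(n_cells, radius_xy_range = c(2, 2.5),
                            radius_z_range = c(2, 2.5), clustering = 0,
                            min_separation = 6,
                            intensity_range = c(0.6, 0.9),
                            allow_boundary_cut = TRUE) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (any(radius_xy_range <= 0) || any(radius_z_range <= 0))
    stop("radius ranges must be positive")
  if (any(intensity_range < 0) || any(intensity_range > 1))
    stop("intensity range must lie in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 radius_xy_range = sort(radius_xy_range),
                 radius_z_range = sort(radius_z_range),
                 clustering = clustering,
                 min_separation = min_separation,
                 intensity_range = sort(intensity_range),
                 allow_boundary_cut = isTRUE(allow_boundary_cut)),
            class = "cell_population")
}

#' Default population for a profile
#'
#' Nuclear labels use 2–2.5 um radii; cytoplasmic labels (whole somata)
#' use 3–4 um.
#'
#' @param profile an [acquisition_profile()].
#' @param n_cells number of cells.
#' @param ... passed on to [cell_population()].
#' @return a `cell_population`.
#' @export
default_population <- function(profile, n_cells, ...) {
  if (profile$label_target == "cytoplasm")
    cell_population(n_cells, radius_xy_range = c(3, 4),
                    radius_z_range = c(3, 4), min_separation = 7, ...)
  else cell_population(n_cells, ...)
}

#' Noise and blur model
#'
#' Additive Gaussian camera noise, optional Poisson photon noise, and an
#' anisotropic Gaussian blur standing in for the out-of-focus axial PSF of
#' widefield imaging of thick sections.
#'
#' @param background_level normalized background intensity (fluorescence).
#' @param gaussian_sd additive noise standard deviation (normalized).
#' @param poisson_scale photons per unit intensity; 0 disables shot noise.
#' @param axial_blur_sd,lateral_blur_sd PSF-blur standard deviations in
#'   micrometres.
#' @return a `noise_model` list.
#' @export
noise_model <- function(background_level = 0.08, gaussian_sd = 0.02,
                        poisson_scale = 0, axial_blur_sd = 0.75,
                        lateral_blur_sd = 0.25) {
  v <- c(background_level, gaussian_sd, poisson_scale, axial_blur_sd,
         lateral_blur_sd)
  if (any(v < 0)) stop("noise parameters must be non-negative")
  structure(list(background_level = background_level,
                 gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 axial_blur_sd = axial_blur_sd,
                 lateral_blur_sd = lateral_blur_sd),
            class = "noise_model")
}

# --- placement ---------------------------------------------------------

# Hard-core (optionally Thomas-clustered) rejection sampling of cell
# centers in physical coordinates. Must run inside with_seed().
place_cells <- function(profile, pop) {
  n <- pop$n_cells
  ext <- profile_extent(profile)
  rxy <- runif(n, pop$radius_xy_range[1], pop$radius_xy_range[2])
  rz <- runif(n, pop$radius_z_range[1], pop$radius_z_range[2])
  intens <- runif(n, pop$intensity_range[1], pop$intensity_range[2])
  if (n == 0L) {
    return(data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      cz = numeric(), rx = numeric(), ry = numeric(),
                      rz = numeric(), intensity = numeric()))
  }
  parents <- NULL
  if (pop$clustering > 0) {
    n_par <- max(1L, ceiling(n / 5))
    parents <- cbind(runif(n_par, 0, ext["x"]), runif(n_par, 0, ext["y"]),
                     runif(n_par, 0, ext["z"]))
  }
  cx <- cy <- cz <- numeric(n)
  max_attempts <- 2000L * n
  attempts <- 0L
  for (i in seq_len(n)) {
    lo <- c(0, 0, 0); hi <- ext
    if (!pop$allow_boundary_cut) {
      lo <- c(rxy[i], rxy[i], rz[i])
      hi <- ext - c(rxy[i], rxy[i], rz[i])
      if (any(hi < lo))
        stop("cells of this size cannot fit inside the stack interior")
    }
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("failed to place %d cells with min_separation ",
                            "%.2f um after %d attempts"),
                     n, pop$min_separation, max_attempts))
      if (is.null(parents)) {
        cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
                  runif(1, lo[3], hi[3]))
      } else {
        p <- parents[sample.int(nrow(parents), 1L), ]
        cand <- p + rnorm(3, 0, pop$clustering)
        if (any(cand < lo) || any(cand > hi)) next
      }
      if (i > 1L) {
        dd <- sqrt((cx[1:(i - 1)] - cand[1])^2 +
                   (cy[1:(i - 1)] - cand[2])^2 +
                   (cz[1:(i - 1)] - cand[3])^2)
        if (any(dd < pop$min_separation)) next
      }
      cx[i] <- cand[1]; cy[i] <- cand[2]; cz[i] <- cand[3]
      break
    }
  }
  data.frame(id = seq_len(n), cx = cx, cy = cy, cz = cz,
             rx = rxy, ry = rxy, rz = rz, intensity = intens)
}

# --- rasterization -----------------------------------------------------

# Voxelize each cell's ellipsoid onto the label grid (first-placed cell
# wins contested voxels) and flag cells whose voxelized support extends
# beyond the stack bounds.
rasterize_cells <- function(cells, profile) {
  sp <- profile_spacing(profile)
  dims <- c(profile$height, profile$width, profile$n_planes)
  labels <- array(0L, dims)
  boundary <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    # unclipped index ranges of the ellipsoid's bounding box (1-based)
    jr <- (floor((cl$cx - cl$rx) / sp["x"]) : ceiling((cl$cx + cl$rx) / sp["x"])) + 1
    ir <- (floor((cl$cy - cl$ry) / sp["y"]) : ceiling((cl$cy + cl$ry) / sp["y"])) + 1
    kr <- (floor((cl$cz - cl$rz) / sp["z"]) : ceiling((cl$cz + cl$rz) / sp["z"])) + 1
    xs <- (jr - 1) * sp["x"]; ys <- (ir - 1) * sp["y"]; zs <- (kr - 1) * sp["z"]
    dx2 <- ((xs - cl$cx) / cl$rx)^2
    dy2 <- ((ys - cl$cy) / cl$ry)^2
    dz2 <- ((zs - cl$cz) / cl$rz)^2
    inside <- outer(outer(dy2, dx2, "+"), dz2, "+") <= 1
    in_bounds <- outer(outer(ir >= 1L & ir <= dims[1],
                             jr >= 1L & jr <= dims[2], "&"),
                       kr >= 1L & kr <= dims[3], "&")
    sel <- which(inside & in_bounds, arr.ind = TRUE)
    # boundary iff the true support leaves the stack or sits on a face
    on_face <- ir[sel[, 1]] %in% c(1L, dims[1]) |
      jr[sel[, 2]] %in% c(1L, dims[2]) | kr[sel[, 3]] %in% c(1L, dims[3])
    boundary[i] <- any(inside & !in_bounds) || any(on_face)
    if (nrow(sel)) {
      lin <- cbind(ir[sel[, 1]], jr[sel[, 2]], kr[sel[, 3]])
      cur <- labels[lin]
      free <- cur == 0L
      if (any(free)) labels[lin[free, , drop = FALSE]] <- cl$id
    }
  }
  list(labels = labels, boundary = boundary)
}

# --- rendering ---------------------------------------------------------

#' Generate a synthetic stack with known ground truth
#'
#' Places ellipsoidal cells (hard-core rejection sampling, optional
#' Thomas-process clustering), voxelizes them into a true label volume,
#' renders an intensity image as the ellipsoid indicators scaled by
#' per-cell intensity and convolved with an anisotropic Gaussian PSF blur,
#' adds background and noise, and quantizes to the requested bit depth.
#' Brightfield profiles are rendered as RGB via [render_brightfield()].
#'
#' Identical inputs and seed reproduce bit-identical outputs; all
#' stochastic draws derive from one master seed split per stage
#' (placement, rendering, noise).
#'
#' @param profile an [acquisition_profile()].
#' @param pop a [cell_population()].
#' @param noise a [noise_model()].
#' @param seed integer master seed.
#' @param depth output bit depth (8 default, 16 optional).
#' @param gt_z `"center"` places ground-truth marker z at the analytic
#'   ellipsoid center; `"median_plane"` snaps it to the nearest image
#'   plane, emulating manual marking of the median plane of appearance.
#' @return list with `stack` (an `image_stack`), `markers` (ground-truth
#'   `marker_set`; `boundary` is 1 exactly when the cell's voxelized
#'   support extends beyond the stack bounds), and `labels` (true
#'   `labeled_volume`).
#' @export
generate_stack <- function(profile, pop, noise = noise_model(), seed,
                           depth = 8L, gt_z = c("center", "median_plane")) {
  gt_z <- match.arg(gt_z)
  stopifnot(inherits(profile, "acquisition_profile"),
            inherits(pop, "cell_population"),
            inherits(noise, "noise_model"))
  seeds <- stage_seeds(seed, 3L)
  sp <- profile_spacing(profile)

  cells <- with_seed(seeds[1], place_cells(profile, pop))
  ras <- rasterize_cells(cells, profile)
  labels <- labeled_volume(ras$labels, spacing = sp)

  signal <- array(0, dim(ras$labels))
  if (nrow(cells)) {
    pos <- ras$labels > 0L
    signal[pos] <- cells$intensity[ras$labels[pos]]
  }
  blur_vox <- c(noise$lateral_blur_sd / sp["x"],
                noise$lateral_blur_sd / sp["y"],
                noise$axial_blur_sd / sp["z"])
  if (any(blur_vox > 0)) signal <- gaussian_smooth_3d(signal, blur_vox)

  if (profile$modality == "brightfield_rgb") {
    stack <- render_brightfield(labels, signal, seed = seeds[3],
                                noise_sd = noise$gaussian_sd, depth = depth)
  } else {
    img <- noise$background_level + signal
    img <- with_seed(seeds[3], {
      if (noise$poisson_scale > 0)
        img <- rpois(length(img), pmax(img, 0) * noise$poisson_scale) /
          noise$poisson_scale
      img + rnorm(length(img), 0, noise$gaussian_sd)
    })
    stack <- image_stack(array(quantize_values(img, depth), dim(signal)),
                         spacing = sp, depth = depth,
                         modality = "fluorescence")
  }

  zc <- cells$cz
  if (gt_z == "median_plane" && length(zc))
    zc <- round(zc / sp["z"]) * sp["z"]
  markers <- marker_set(cells$id, cells$cx, cells$cy, zc,
                        boundary = as.integer(ras$boundary), spacing = sp)
  list(stack = stack, markers = markers, labels = labels)
}

#' Render a brightfield RGB stack from a label/intensity pair
#'
#' Background is bright and approximately neutral; cell voxels are blended
#' toward a DAB-brown color in proportion to the (blurred) label signal, so
#' cells are darker than the background in the red channel while their red
#' chromaticity r = R/(R+G+B) is higher than the neutral background's 1/3.
#'
#' @param labels a `labeled_volume` (geometry reference).
#' @param intensity_stack real-valued 3D array/stack in \[0, 1\]: the cell
#'   signal (e.g. the blurred ellipsoid rendering).
#' @param seed integer seed for the noise draw.
#' @param background_level neutral background level (normalized).
#' @param cell_color DAB-brown RGB triple (normalized).
#' @param noise_sd per-channel additive Gaussian noise sd.
#' @param depth output bit depth.
#' @return an RGB `image_stack`.
#' @export
render_brightfield <- function(labels, intensity_stack, seed,
                               background_level = 0.9,
                               cell_color = c(0.55, 0.35, 0.20),
                               noise_sd = 0.02, depth = 8L) {
  a <- unclass(intensity_stack)
  if (!identical(dim(a), dim(unclass(labels))))
    stop("`labels` and `intensity_stack` must share geometry")
  w <- clip01(a)  # blend weight toward the stain color
  d <- dim(a)
  rgb <- array(0, c(d, 3L))
  for (ch in 1:3)
    rgb[, , , ch] <- background_level * (1 - w) + cell_color[ch] * w
  rgb <- with_seed(seed, rgb + rnorm(length(rgb), 0, noise_sd))
  image_stack(quantize_values(rgb, depth), spacing = attr(labels, "spacing"),
              depth = depth, modality = "brightfield_rgb",
              channels = c("R", "G", "B"))
}

#' Contrast-to-noise ratio of a rendered stack
#'
#' `(mean(foreground) - mean(background)) / sd(background)` using the true
#' label volume to define foreground. Used to verify that heavier noise
#' degrades the rendered contrast.
#'
#' @param stack grayscale `image_stack`.
#' @param labels the true `labeled_volume`.
#' @return numeric CNR.
#' @export
contrast_to_noise <- function(stack, labels) {
  a <- unclass(stack)
  fg <- unclass(labels) > 0L
  (mean(a[fg]) - mean(a[!fg])) / sd(a[!fg])
}
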