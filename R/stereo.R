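# Unbiased 3D stereologic counting rules: the counting frame with
# inclusion/exclusion edges, the top-of-cell rule inside an unbiased
# virtual counting space (UVCS), the fractionator total-number estimate,
# and a simulation of the 2D profile-counting bias these rules remove.

#' Unbiased virtual counting space geometry
#'
#' A rectangular counting frame in XY plus a counting depth interval in Z
#' placed within the section thickness (the guard zones are whatever the
#' interval leaves above and below). Exclusion edges follow the classic
#' unbiased counting frame convention: the left and bottom edges, extended
#' by a vertical ray upward from the top-left corner and a vertical ray
#' downward from the bottom-right corner. The top and right edges are
#' inclusion edges.
#'
#' @param frame_origin `(x, y)` of the bottom-left corner, micrometres.
#' @param frame_size `(w, h)` of the frame, micrometres.
#' @param z_top,z_bottom counting depth interval within the section,
#'   micrometres (z grows downward into the section; `z_top < z_bottom`).
#' @return a `uvcs_geometry` list.
#' @export
uvcs_geometry <- function(frame_origin = c(0, 0), frame_size = c(30, 30),
                          z_top = 2, z_bottom = 12) {
  if (any(frame_size <= 0)) stop("frame size must be positive")
  if (!(z_top < z_bottom)) stop("z_top must be smaller than z_bottom")
  structure(list(x0 = frame_origin[1], y0 = frame_origin[2],
                 w = frame_size[1], h = frame_size[2],
                 z_top = z_top, z_bottom = z_bottom),
            class = "uvcs_geometry")
}

#' Cell records for stereologic rule evaluation
#'
#' Cells are represented by a circular XY footprint (radius `r`) and a
#' "top": the Z position where the cell first comes into focus when
#' focusing down through the section. Cells cut at the section top during
#' histologic sectioning have their top in the section above; flag these
#' with `top_in_section = FALSE`.
#'
#' @param x,y,z centroid coordinates, micrometres.
#' @param r footprint radius, micrometres (> 0).
#' @param top_z top-of-cell depth; defaults to `z - r` (spherical proxy).
#' @param top_in_section logical; `FALSE` if the top lies in the previous
#'   section.
#' @return a `cell_records` data frame.
#' @export
cell_records <- function(x, y, z, r, top_z = z - r,
                         top_in_section = TRUE) {
  if (any(r <= 0)) stop("footprint radius must be positive")
  n <- length(x)
  df <- data.frame(x = x, y = y, z = z, r = r, top_z = top_z,
                   top_in_section = rep_len(top_in_section, n))
  if (any(df$top_z > df$z + 1e-12)) stop("top_z must not exceed centroid z")
  structure(df, class = c("cell_records", "data.frame"))
}

# distance from points to a segment (vectorized over points)
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Classify cell footprints against the unbiased counting frame
#'
#' A cell is `"counted"` iff its footprint lies entirely within the frame
#' or intersects only inclusion edges (top/right); it is `"excluded"` if it
#' touches any exclusion edge or their infinite extensions, or if it does
#' not reach the frame at all.
#'
#' @param cells a [cell_records()] data frame.
#' @param frame a [uvcs_geometry()].
#' @return character vector, `"counted"` or `"excluded"` per cell.
#' @export
frame_classify <- function(cells, frame) {
  if (!nrow(cells)) return(character())
  x0 <- frame$x0; y0 <- frame$y0
  x1 <- x0 + frame$w; y1 <- y0 + frame$h
  L <- 1e6  # effectively infinite edge extensions
  px <- cells$x; py <- cells$y; r <- cells$r
  # exclusion polyline: up-ray from top-left, left edge, bottom edge,
  # down-ray from bottom-right
  d_excl <- pmin(
    dist_point_segment(px, py, x0, y0, x0, y1 + L),
    dist_point_segment(px, py, x0, y0, x1, y0),
    dist_point_segment(px, py, x1, y0, x1, y0 - L))
  excluded <- d_excl <= r
  # circle-rectangle intersection (closed frame)
  dx <- pmax(x0 - px, 0, px - x1)
  dy <- pmax(y0 - py, 0, py - y1)
  touches_frame <- sqrt(dx^2 + dy^2) <= r
  ifelse(!excluded & touches_frame, "counted", "excluded")
}

#' Top-of-cell rule for the UVCS depth interval
#'
#' `TRUE` iff the cell's top lies within this section and within the
#' counting depth interval `[z_top, z_bottom]`.
#'
#' @param cells a [cell_records()] data frame.
#' @param frame a [uvcs_geometry()].
#' @return logical vector per cell.
#' @export
top_in_uvcs <- function(cells, frame) {
  cells$top_in_section & cells$top_z >= frame$z_top &
    cells$top_z <= frame$z_bottom
}

#' Count cells under the full 3D stereologic rules
#'
#' A cell is counted iff it passes both the counting-frame rule
#' ([frame_classify()] returns `"counted"`) and the top-of-cell rule
#' ([top_in_uvcs()]).
#'
#' @param cells a [cell_records()] data frame.
#' @param frame a [uvcs_geometry()].
#' @return list with `count` and a per-cell `classification` data frame
#'   (`frame`, `top_ok`, `counted`).
#' @export
uvcs_count <- function(cells, frame) {
  fc <- frame_classify(cells, frame)
  tk <- top_in_uvcs(cells, frame)
  counted <- fc == "counted" & tk
  list(count = sum(counted),
       classification = data.frame(frame = fc, top_ok = tk,
                                   counted = counted))
}

#' Three-cell demonstration configuration
#'
#' The canonical didactic configuration: cell 1 lies inside the frame with
#' its top inside the UVCS (counted); cell 2 crosses only an inclusion edge
#' but was cut at sectioning, so its top is in the section above (not
#' counted); cell 3 touches the left exclusion edge and its top lies in the
#' upper guard zone (not counted). Exactly one cell satisfies all 3D rules.
#'
#' @return list with `cells` ([cell_records()]) and `frame`
#'   ([uvcs_geometry()]).
#' @export
uvcs_demo_configuration <- function() {
  frame <- uvcs_geometry(frame_origin = c(0, 0), frame_size = c(10, 10),
                         z_top = 2, z_bottom = 8)
  cells <- cell_records(
    x = c(5.0, 5.0, 0.5),
    y = c(5.0, 10.5, 5.0),
    z = c(5.5, 4.5, 2.5),
    r = c(1.5, 1.5, 1.5),
    top_z = c(4.0, 3.0, 1.0),
    top_in_section = c(TRUE, FALSE, TRUE))
  list(cells = cells, frame = frame)
}

#' Sampling design fractions
#'
#' @param section_fraction fraction of sections sampled (e.g. every 10th
#'   section is 1/10).
#' @param area_fraction frame area over grid-cell area.
#' @param height_fraction UVCS depth over section thickness.
#' @return a `sampling_design` list.
#' @export
sampling_design <- function(section_fraction, area_fraction,
                            height_fraction) {
  f <- c(section_fraction, area_fraction, height_fraction)
  if (any(f <= 0) || any(f > 1)) stop("fractions must lie in (0, 1]")
  structure(list(section_fraction = section_fraction,
                 area_fraction = area_fraction,
                 height_fraction = height_fraction),
            class = "sampling_design")
}

#' Fractionator estimate of total cell number
#'
#' The standard fractionator product: the raw count Q over all sampled
#' counting spaces divided by the product of the sampling fractions.
#'
#' @param q total number of cells counted in the sampled UVCSs.
#' @param design a [sampling_design()].
#' @return estimated total number.
#' @export
estimate_total <- function(q, design) {
  stopifnot(inherits(design, "sampling_design"))
  q / (design$section_fraction * design$area_fraction *
         design$height_fraction)
}

#' Fractionator unbiasedness simulation
#'
#' Scatters `n_cells` point-like cells uniformly in a block of tissue,
#' samples sections systematically with a random start, places a
#' systematically random grid of counting frames per sampled section
#' (toroidal wrap, so every location has equal inclusion probability),
#' counts by the 3D rules, and returns one fractionator estimate per
#' replicate. The mean estimate converges on `n_cells`.
#'
#' @param n_cells true number of cells.
#' @param region `(x, y, z)` block dimensions, micrometres.
#' @param section_thickness section thickness, micrometres (must divide
#'   the region depth).
#' @param section_period sample every `section_period`-th section.
#' @param frame_size `(w, h)` counting frame, micrometres.
#' @param grid_spacing `(gx, gy)` grid pitch, micrometres (must divide the
#'   region extent).
#' @param uvcs_depth counting depth per section, micrometres.
#' @param guard upper guard-zone height, micrometres.
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return numeric vector of `n_rep` estimates, with the true count in
#'   attribute `true_n`.
#' @export
fractionator_simulation <- function(n_cells = 2000,
                                    region = c(200, 200, 60),
                                    section_thickness = 10,
                                    section_period = 2,
                                    frame_size = c(25, 25),
                                    grid_spacing = c(50, 50),
                                    uvcs_depth = 6, guard = 2,
                                    n_rep = 200, seed = 1) {
  n_sections <- region[3] / section_thickness
  stopifnot(n_sections == round(n_sections),
            region[1] %% grid_spacing[1] == 0,
            region[2] %% grid_spacing[2] == 0,
            guard + uvcs_depth <= section_thickness)
  design <- sampling_design(1 / section_period,
                            prod(frame_size) / prod(grid_spacing),
                            uvcs_depth / section_thickness)
  seeds <- stage_seeds(seed, n_rep)
  eps <- 1e-6  # point-like footprint
  estimates <- vapply(seq_len(n_rep), function(rep) {
    with_seed(seeds[rep], {
      cx <- runif(n_cells, 0, region[1])
      cy <- runif(n_cells, 0, region[2])
      cz <- runif(n_cells, 0, region[3])
      start <- sample.int(section_period, 1L)
      q <- 0L
      for (s in seq(start, n_sections, by = section_period)) {
        sec_lo <- (s - 1) * section_thickness
        in_sec <- cz >= sec_lo & cz < sec_lo + section_thickness
        if (!any(in_sec)) next
        ox <- runif(1, 0, grid_spacing[1])
        oy <- runif(1, 0, grid_spacing[2])
        frame <- uvcs_geometry(c(0, 0), frame_size,
                               z_top = guard, z_bottom = guard + uvcs_depth)
        for (kx in seq_len(region[1] / grid_spacing[1]) - 1L) {
          for (ky in seq_len(region[2] / grid_spacing[2]) - 1L) {
            # toroidal coordinates relative to this frame's origin
            rx <- (cx[in_sec] - ox - kx * grid_spacing[1]) %% region[1]
            ry <- (cy[in_sec] - oy - ky * grid_spacing[2]) %% region[2]
            cells <- cell_records(rx, ry, cz[in_sec] - sec_lo, r = eps,
                                  top_z = cz[in_sec] - sec_lo)
            q <- q + uvcs_count(cells, frame)$count
          }
        }
      }
      estimate_total(q, design)
    })
  }, numeric(1))
  attr(estimates, "true_n") <- n_cells
  estimates
}

#' Demonstrate the 2D profile-counting bias
#'
#' Populations with the same true cell number but different diameters are
#' sectioned virtually. Counting 2D profiles (a cell contributes whenever
#' the thin section intersects its sphere) yields counts that grow with
#' cell diameter — expected count `N * (d + t) / H` for diameter d, section
#' thickness t, block depth H — whereas UVCS counting by the top-of-cell
#' rule is size-independent. Point-like populations (`diameter = 0`) yield
#' zero profiles under a zero-thickness section.
#'
#' @param diameters cell diameters per population, micrometres.
#' @param n_cells true number of cells in every population.
#' @param section_thickness thin-section thickness t, micrometres.
#' @param block_depth depth H of the virtual tissue block, micrometres.
#' @param uvcs_window `(z1, z2)` counting depth window for the top rule.
#' @param n_rep replicates to average over.
#' @param seed integer seed.
#' @return data frame with one row per population: `diameter_um`,
#'   `true_n`, mean/sd of profile and UVCS counts, and the closed-form
#'   `expected_profiles`.
#' @export
profile_count_bias_demo <- function(diameters = c(5, 10), n_cells = 200,
                                    section_thickness = 2,
                                    block_depth = 100,
                                    uvcs_window = c(10, 40),
                                    n_rep = 200, seed = 1) {
  rmax <- max(diameters) / 2
  stopifnot(uvcs_window[2] <= block_depth - rmax,
            uvcs_window[1] >= 0)
  seeds <- stage_seeds(seed, n_rep)
  res <- lapply(diameters, function(d) {
    r <- d / 2
    counts <- vapply(seq_len(n_rep), function(rep) {
      with_seed(seeds[rep] + match(d, diameters), {
        cz <- runif(n_cells, 0, block_depth)
        # thin section placed clear of the block faces
        z0 <- runif(1, rmax, block_depth - section_thickness - rmax)
        profiles <- sum(cz >= z0 - r & cz <= z0 + section_thickness + r)
        tops <- cz - r
        uvcs <- sum(tops >= uvcs_window[1] & tops <= uvcs_window[2])
        c(profiles, uvcs)
      })
    }, numeric(2))
    data.frame(diameter_um = d, true_n = n_cells,
               profile_mean = mean(counts[1, ]),
               profile_sd = sd(counts[1, ]),
               uvcs_mean = mean(counts[2, ]),
               uvcs_sd = sd(counts[2, ]),
               expected_profiles = n_cells * (d + section_thickness) /
                 block_depth,
               n_rep = n_rep)
  })
  do.call(rbind, res)
}
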