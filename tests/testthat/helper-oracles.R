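# Independent oracles used across the suite. Each deliberately uses a
# different algorithm than the implementation it checks.

# Canonical relabeling: labels renumbered by first occurrence in linear
# (storage) order, so two labelings of the same partition become equal.
canonical_labels <- function(a) {
  a <- unclass(a)
  idx <- which(a > 0)
  if (!length(idx)) return(array(0L, dim(a)))
  labs <- a[idx]
  firsts <- labs[!duplicated(labs)]
  map <- integer(max(labs))
  map[firsts] <- seq_along(firsts)
  out <- array(0L, dim(a))
  out[idx] <- map[labs]
  out
}

# Shift a 3D array by offset o = c(dy, dx, dz), zero-filling.
shift_array3 <- function(a, o) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (o[ax] >= 0) {
      dst[[ax]] <- seq(1 + o[ax], d[ax])
      src[[ax]] <- seq(1, d[ax] - o[ax])
    } else {
      dst[[ax]] <- seq(1, d[ax] + o[ax])
      src[[ax]] <- seq(1 - o[ax], d[ax])
    }
    if (abs(o[ax]) >= d[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  g <- g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
  man <- abs(g$dy) + abs(g$dx) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = man == 1, "18" = man <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

# Connected components by iterated min-label propagation (fixpoint),
# a different algorithm than the package's flood fill.
oracle_cc <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  offs <- neighbor_offsets(connectivity)
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      s <- shift_array3(lab, offs[r, ])
      sel <- mask & s > 0 & s < new
      new[sel] <- s[sel]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  canonical_labels(lab)
}

# Explicit-enumeration centroid oracle (0-based voxel coordinates).
oracle_centroids <- function(vol) {
  a <- unclass(vol)
  labs <- sort(unique(a[a > 0]))
  t(vapply(labs, function(l) {
    w <- which(a == l, arr.ind = TRUE)
    c(x = mean(w[, 2] - 1), y = mean(w[, 1] - 1), z = mean(w[, 3] - 1))
  }, numeric(3)))
}

# Face-scan oracle for boundary touching.
oracle_face_flags <- function(vol) {
  a <- unclass(vol)
  d <- dim(a)
  n <- max(a)
  vapply(seq_len(n), function(l) {
    w <- which(a == l, arr.ind = TRUE)
    any(w[, 1] %in% c(1, d[1]) | w[, 2] %in% c(1, d[2]) |
          w[, 3] %in% c(1, d[3]))
  }, logical(1))
}

# Direct-summation Gaussian convolution (triple loop over kernel taps),
# symmetric boundary reflection, 4-sigma truncation — matches the
# contract, not the implementation.
oracle_gauss <- function(a, sig) {
  kern <- function(s) {
    if (s == 0) return(1)
    r <- max(1, ceiling(4 * s))
    k <- dnorm(-r:r, sd = s)
    k / sum(k)
  }
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  kx <- kern(sig[1]); ky <- kern(sig[2]); kz <- kern(sig[3])
  ry <- (length(ky) - 1) / 2; rx <- (length(kx) - 1) / 2
  rz <- (length(kz) - 1) / 2
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a1 in seq_along(ky)) for (a2 in seq_along(kx))
      for (a3 in seq_along(kz)) {
        ii <- reflect(i + a1 - ry - 1, d[1])
        jj <- reflect(j + a2 - rx - 1, d[2])
        kk <- reflect(k + a3 - rz - 1, d[3])
        acc <- acc + ky[a1] * kx[a2] * kz[a3] * a[ii, jj, kk]
      }
    out[i, j, k] <- acc
  }
  out
}

# Optimal (maximum-cardinality) assignment of detections to ground truth
# within the tolerance cylinder — the upper bound for greedy matching.
oracle_optimal_tp <- function(gt, det, tol) {
  n <- nrow(gt); m <- nrow(det)
  if (n == 0 || m == 0) return(0L)
  dxy <- sqrt(outer(gt$x_um, det$x_um, "-")^2 +
                outer(gt$y_um, det$y_um, "-")^2)
  dz <- abs(outer(gt$z_um, det$z_um, "-"))
  elig <- which(dxy <= tol$r_xy & dz <= tol$r_z, arr.ind = TRUE)
  if (!nrow(elig)) return(0L)
  g <- igraph::make_empty_graph(n + m, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(cbind(elig[, 1], n + elig[, 2]))))
  igraph::V(g)$type <- c(rep(FALSE, n), rep(TRUE, m))
  igraph::max_bipartite_match(g)$matching_size
}

# Random seeded binary mask.
random_mask <- function(dims, p, seed) {
  stereobench:::with_seed(seed, array(runif(prod(dims)) < p, dims))
}

# Small acquisition profile for unit tests (coarse spacing keeps arrays
# tiny while cell radii stay at realistic micrometre scales).
tiny_profile <- function(width = 48, height = 48, n_planes = 14,
                         sx = 0.46056, sy = 0.46056, sz = 1,
                         modality = "fluorescence") {
  acquisition_profile("tiny", sx, sy, sz, width, height, n_planes,
                      modality = modality, label_target = "nucleus",
                      min_voxels = 25L)
}

# Geometric reconstruction of a benchmark row: lays out n_gt ground-truth
# markers on a wide grid (spacing 8 um, so matching is unambiguous),
# detects all but `miss_boundary` + `miss_interior` of them, and adds
# `n_fp` far-away false detections.
reconstruct_row_markers <- function(n_gt, n_interior, n_miss_boundary,
                                    n_miss_interior, n_fp) {
  pitch <- 8
  ncol_grid <- ceiling(sqrt(n_gt))
  ix <- (seq_len(n_gt) - 1) %% ncol_grid
  iy <- (seq_len(n_gt) - 1) %/% ncol_grid
  gt <- marker_set(seq_len(n_gt), ix * pitch, iy * pitch,
                   rep(c(0, 4), length.out = n_gt) * 0 + (ix %% 3),
                   boundary = c(rep(0L, n_interior),
                                rep(1L, n_gt - n_interior)))
  miss <- c(if (n_miss_interior > 0) seq_len(n_miss_interior),
            if (n_miss_boundary > 0) n_interior + seq_len(n_miss_boundary))
  det_rows <- setdiff(seq_len(n_gt), miss)
  fx <- ((seq_len(n_fp) - 1) %% ncol_grid) * pitch + 4000
  fy <- ((seq_len(n_fp) - 1) %/% ncol_grid) * pitch
  det <- marker_set(seq_len(length(det_rows) + n_fp),
                    c(gt$x_um[det_rows] + 0.4, fx),
                    c(gt$y_um[det_rows] - 0.3, fy),
                    c(gt$z_um[det_rows] + 0.5, rep(0, n_fp)))
  list(gt = gt, det = det)
}
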