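# Evaluation core: greedy centroid matching within a cylindrical tolerance,
# TP/FN/FP classification, rate computation, interior/boundary
# stratification, and multi-method combination.

#' Cylindrical matching tolerance
#'
#' The search region around each ground-truth centroid is a cylinder: a
#' lateral radius in XY (default 3 um, the lower end of observed nucleus
#' radii) and an axial half-height in Z (1.5 um, or 2.0 um for
#' low-numerical-aperture acquisitions). The cylinder reflects the lower
#' axial precision of light microscopy.
#'
#' @param r_xy lateral tolerance radius, micrometres.
#' @param r_z axial tolerance half-height, micrometres.
#' @return a `tolerance_spec` list.
#' @export
tolerance_spec <- function(r_xy = 3.0, r_z = 1.5) {
  if (r_xy <= 0 || r_z <= 0) stop("tolerances must be positive")
  structure(list(r_xy = r_xy, r_z = r_z), class = "tolerance_spec")
}

check_same_frame <- function(a, b) {
  sa <- attr(a, "spacing"); sb <- attr(b, "spacing")
  if (!is.null(sa) && !is.null(sb) &&
      !isTRUE(all.equal(as.numeric(sa), as.numeric(sb), tolerance = 1e-9)))
    stop("marker sets declare different voxel spacings (coordinate frames)")
  invisible(TRUE)
}

#' Match detections to ground truth within a cylindrical tolerance
#'
#' One greedy pass over the ground-truth markers: for each, the eligible
#' detections (lateral distance <= `r_xy` and |dz| <= `r_z`, not yet
#' consumed) are inspected and the nearest is taken, marking the
#' ground-truth cell a true-positive and removing that detection from
#' further consideration; otherwise the cell is a false-negative. Leftover
#' detections are false-positives. Boundary-flagged ground-truth cells are
#' matched like all others; stratification is post hoc.
#'
#' "Nearest" uses the normalized elliptic distance
#' `sqrt((dxy/r_xy)^2 + (dz/r_z)^2)` by default, which respects the
#' anisotropy that motivates the cylindrical region; plain Euclidean
#' distance is available. Ties break to the lowest detection id. Greedy
#' results can depend on ground-truth order; `order = "sorted"`
#' (lexicographic by coordinates) gives a canonical run.
#'
#' @param gt ground-truth `marker_set` (with boundary flags).
#' @param det detection `marker_set`.
#' @param tol a [tolerance_spec()].
#' @param metric `"normalized"` or `"euclidean"`.
#' @param order `"file"` (input order) or `"sorted"`.
#' @return a `match_result`: list with `assignments` (data frame `gt_id`,
#'   `det_id`, `class` in TP/FN/FP), counts `n_gt`, `n_gti`, `n_s`, `n_tp`,
#'   `n_fn`, `n_fp`, rates `r_tp`, `r_tpi`, `r_tpb`, `r_fp`, and the input
#'   marker sets.
#' @export
match_markers <- function(gt, det, tol = tolerance_spec(),
                          metric = c("normalized", "euclidean"),
                          order = c("file", "sorted")) {
  metric <- match.arg(metric)
  order <- match.arg(order)
  stopifnot(inherits(tol, "tolerance_spec"))
  check_same_frame(gt, det)

  gi <- seq_len(nrow(gt))
  if (order == "sorted" && nrow(gt))
    gi <- order(gt$x_um, gt$y_um, gt$z_um)

  used <- rep(FALSE, nrow(det))
  det_of_gt <- rep(NA_integer_, nrow(gt))  # row index into det
  for (g in gi) {
    if (!nrow(det)) break
    dxy <- sqrt((det$x_um - gt$x_um[g])^2 + (det$y_um - gt$y_um[g])^2)
    dz <- abs(det$z_um - gt$z_um[g])
    elig <- !used & dxy <= tol$r_xy & dz <= tol$r_z
    if (!any(elig)) next
    score <- if (metric == "normalized")
      sqrt((dxy / tol$r_xy)^2 + (dz / tol$r_z)^2)
    else sqrt(dxy^2 + dz^2)
    score[!elig] <- Inf
    # nearest; ties break to lowest detection id
    best <- which(score == min(score))
    best <- best[which.min(det$id[best])]
    used[best] <- TRUE
    det_of_gt[g] <- best
  }

  assignments <- data.frame(
    gt_id = c(gt$id, rep(NA_integer_, sum(!used))),
    det_id = c(det$id[det_of_gt], det$id[!used]),
    class = c(ifelse(is.na(det_of_gt), "FN", "TP"), rep("FP", sum(!used))),
    stringsAsFactors = FALSE)

  finish_match_result(assignments, gt, det, tol)
}

# Assemble counts/rates from an assignment table; shared with combiners.
finish_match_result <- function(assignments, gt, det, tol,
                                n_s = nrow(det)) {
  tp_rows <- assignments$class == "TP"
  n_tp <- sum(tp_rows)
  n_fn <- sum(assignments$class == "FN")
  n_fp <- sum(assignments$class == "FP")
  n_gt <- nrow(gt)
  n_gti <- sum(gt$boundary == 0L)
  r <- detection_rates(n_tp, n_fn, n_fp, n_gt, n_s, warn = FALSE)

  interior_ids <- gt$id[gt$boundary == 0L]
  tp_ids <- assignments$gt_id[tp_rows]
  n_tpi <- sum(tp_ids %in% interior_ids)
  r_tpi <- if (n_gti > 0) n_tpi / n_gti else 0
  n_b <- n_gt - n_gti
  r_tpb <- if (n_b > 0) (n_tp - n_tpi) / n_b else 0

  structure(list(assignments = assignments,
                 n_gt = n_gt, n_gti = n_gti, n_s = n_s,
                 n_tp = n_tp, n_fn = n_fn, n_fp = n_fp,
                 r_tp = r[["r_tp"]], r_tpi = r_tpi, r_tpb = r_tpb,
                 r_fp = r[["r_fp"]],
                 gt = gt, det = det, tol = tol),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> N_gt=%d (interior %d), N_s=%d: TP=%d FN=%d FP=%d | R_tp=%s R_fp=%s\n",
    x$n_gt, x$n_gti, x$n_s, x$n_tp, x$n_fn, x$n_fp,
    format_rate(x$r_tp), format_rate(x$r_fp)))
  invisible(x)
}

#' True-positive and false-positive rates
#'
#' `R_tp = N_tp / N_gt` (matched ground truth over all ground truth) and
#' `R_fp = N_fp / N_s` (unmatched detections over all detections), as exact
#' rational divisions; rounding happens only at reporting time
#' ([format_rate()]). A zero denominator yields a rate of 0 with a warning.
#'
#' @param n_tp,n_fn,n_fp,n_gt,n_s counts; the identities
#'   `n_tp + n_fn = n_gt` and `n_tp + n_fp = n_s` must hold.
#' @param warn warn on zero denominators.
#' @return named numeric `c(r_tp=, r_fp=)`.
#' @export
detection_rates <- function(n_tp, n_fn, n_fp, n_gt, n_s, warn = TRUE) {
  if (n_tp + n_fn != n_gt)
    stop("count identity violated: n_tp + n_fn != n_gt")
  if (n_tp + n_fp != n_s)
    stop("count identity violated: n_tp + n_fp != n_s")
  r_tp <- if (n_gt > 0) n_tp / n_gt else {
    if (warn) warning("N_gt = 0; R_tp defined as 0"); 0 }
  r_fp <- if (n_s > 0) n_fp / n_s else {
    if (warn) warning("N_s = 0; R_fp defined as 0"); 0 }
  c(r_tp = r_tp, r_fp = r_fp)
}

#' Interior/boundary-stratified true-positive rates
#'
#' `R_tpi` is the true-positive rate over ground-truth cells completely
#' contained in the stack (interior; count `N_gti`); `R_tpb` over the cells
#' that intersect the stack boundary.
#'
#' @param result a `match_result`.
#' @param gt the ground-truth `marker_set` (defaults to the one stored in
#'   `result`).
#' @return named numeric `c(r_tpi=, r_tpb=)`.
#' @export
stratified_rates <- function(result, gt = result$gt) {
  interior_ids <- gt$id[gt$boundary == 0L]
  boundary_ids <- gt$id[gt$boundary == 1L]
  tp_ids <- result$assignments$gt_id[result$assignments$class == "TP"]
  n_gti <- length(interior_ids)
  n_b <- length(boundary_ids)
  r_tpi <- if (n_gti > 0) sum(tp_ids %in% interior_ids) / n_gti else {
    warning("empty interior stratum; R_tpi defined as 0"); 0 }
  r_tpb <- if (n_b > 0) sum(tp_ids %in% boundary_ids) / n_b else {
    warning("empty boundary stratum; R_tpb defined as 0"); 0 }
  c(r_tpi = r_tpi, r_tpb = r_tpb)
}

# FP detection markers of a result (rows of det unmatched).
fp_markers <- function(result) {
  fp_ids <- result$assignments$det_id[result$assignments$class == "FP"]
  result$det[result$det$id %in% fp_ids, , drop = FALSE]
}

# Greedy mutual pairing of two marker tables within the cylinder: all
# eligible cross pairs sorted by normalized distance, accepted when both
# ends are unused. Returns number of pairs.
greedy_pair_count <- function(a, b, tol) {
  if (!nrow(a) || !nrow(b)) return(0L)
  dxy <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
  dz <- abs(outer(a$z_um, b$z_um, "-"))
  elig <- sqrt(dxy) <= tol$r_xy & dz <= tol$r_z
  if (!any(elig)) return(0L)
  score <- sqrt(dxy / tol$r_xy^2 + (dz / tol$r_z)^2)
  ord <- order(score)
  ord <- ord[elig[ord]]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  npair <- 0L
  for (k in ord) {
    i <- ((k - 1) %% nrow(a)) + 1
    j <- ((k - 1) %/% nrow(a)) + 1
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    npair <- npair + 1L
  }
  npair
}

check_same_gt <- function(a, b) {
  if (!isTRUE(all.equal(a$gt, b$gt)))
    stop("results were evaluated against different ground truth")
}

#' Combine two evaluation results as a union
#'
#' Models running both detection methods simultaneously: a ground-truth
#' cell is a true-positive iff it is a true-positive in either result; the
#' false-positive set is the pooled false-positive centroids of both.
#' Pooled false-positives lying mutually within the matching tolerance are
#' merged into one combined false-positive by default (`dedup = TRUE`,
#' greedy nearest pairing); `dedup = FALSE` keeps the plain pooled count.
#' The combined segmentation count is defined as
#' `N_s = N_tp + N_fp`, preserving the count identities.
#'
#' @param a,b `match_result`s evaluated against the same ground truth.
#' @param gt the shared ground-truth `marker_set`.
#' @param tol a [tolerance_spec()] used for false-positive deduplication.
#' @param dedup merge mutually-close false-positives.
#' @return a `match_result`.
#' @export
combine_union <- function(a, b, gt = a$gt, tol = a$tol, dedup = TRUE) {
  check_same_gt(a, b)
  tp_a <- a$assignments[a$assignments$class == "TP", c("gt_id", "det_id")]
  tp_b <- b$assignments[b$assignments$class == "TP", c("gt_id", "det_id")]
  tp_ids <- union(tp_a$gt_id, tp_b$gt_id)
  fa <- fp_markers(a); fb <- fp_markers(b)
  n_fp <- nrow(fa) + nrow(fb)
  if (dedup) n_fp <- n_fp - greedy_pair_count(fa, fb, tol)

  det_id_for <- function(id) {
    i <- match(id, tp_a$gt_id)
    if (!is.na(i)) tp_a$det_id[i] else tp_b$det_id[match(id, tp_b$gt_id)]
  }
  assignments <- data.frame(
    gt_id = c(gt$id, rep(NA_integer_, n_fp)),
    det_id = c(vapply(gt$id, function(id)
      if (id %in% tp_ids) det_id_for(id) else NA_integer_, integer(1)),
      rep(NA_integer_, n_fp)),
    class = c(ifelse(gt$id %in% tp_ids, "TP", "FN"), rep("FP", n_fp)),
    stringsAsFactors = FALSE)
  n_s <- length(tp_ids) + n_fp
  res <- finish_match_result(assignments, gt, a$det, tol, n_s = n_s)
  res$det <- NULL  # combined result has no single detection set
  res
}

#' Combine two evaluation results as an intersection
#'
#' An object must be found by both methods to count: a ground-truth cell is
#' a true-positive iff it is a true-positive in both results, and a
#' combined false-positive is a mutually-close pair (within the tolerance
#' cylinder, greedy nearest pairing) of false-positives from the two
#' results; unpaired false-positives are dropped.
#'
#' @inheritParams combine_union
#' @return a `match_result`.
#' @export
combine_intersection <- function(a, b, gt = a$gt, tol = a$tol) {
  check_same_gt(a, b)
  tp_a <- a$assignments[a$assignments$class == "TP", c("gt_id", "det_id")]
  tp_b <- b$assignments[b$assignments$class == "TP", c("gt_id", "det_id")]
  tp_ids <- intersect(tp_a$gt_id, tp_b$gt_id)
  n_fp <- greedy_pair_count(fp_markers(a), fp_markers(b), tol)
  assignments <- data.frame(
    gt_id = c(gt$id, rep(NA_integer_, n_fp)),
    det_id = c(tp_a$det_id[match(gt$id, tp_a$gt_id)] *
                 ifelse(gt$id %in% tp_ids, 1L, NA_integer_),
               rep(NA_integer_, n_fp)),
    class = c(ifelse(gt$id %in% tp_ids, "TP", "FN"), rep("FP", n_fp)),
    stringsAsFactors = FALSE)
  n_s <- length(tp_ids) + n_fp
  res <- finish_match_result(assignments, gt, a$det, tol, n_s = n_s)
  res$det <- NULL
  res
}
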