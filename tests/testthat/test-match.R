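mk <- function(x, y = rep(0, length(x)), z = rep(0, length(x)),
               boundary = rep(0L, length(x)), id = seq_along(x)) {
  marker_set(id, x, y, z, boundary = boundary)
}

test_that("degenerate matchings behave per the rate definitions", {
  tol <- tolerance_spec(3, 1.5)
  m <- match_markers(mk(seq(0, 60, 10)), mk(numeric(0)), tol)
  expect_equal(c(m$n_tp, m$n_fn, m$n_fp), c(0L, 7L, 0L))
  expect_equal(m$r_tp, 0)
  gt <- mk(seq(0, 90, 10))
  m2 <- match_markers(gt, gt, tol)
  expect_equal(m2$n_tp, 10L)
  expect_equal(c(m2$r_tp, m2$r_fp), c(1, 0))
})

test_that("cylinder membership is lateral radius AND axial half-height", {
  tol <- tolerance_spec(3, 1.5)
  gt <- mk(0)
  hit <- match_markers(gt, mk(2.9, 0, 1.4), tol)
  expect_equal(hit$n_tp, 1L)
  miss_xy <- match_markers(gt, mk(3.1, 0, 0), tol)
  expect_equal(miss_xy$n_tp, 0L)
  expect_equal(miss_xy$n_fp, 1L)
  miss_z <- match_markers(gt, mk(0, 0, 1.6), tol)
  expect_equal(miss_z$n_tp, 0L)
})

test_that("one detection between two close cells yields one TP either order", {
  tol <- tolerance_spec(3, 1.5)
  det <- mk(2)
  for (ord in list(c(0, 4), c(4, 0))) {
    m <- match_markers(mk(ord), det, tol)
    expect_equal(c(m$n_tp, m$n_fn, m$n_fp), c(1L, 1L, 0L))
  }
})

test_that("matched detections are consumed and ties break to lowest id", {
  tol <- tolerance_spec(3, 1.5)
  gt <- mk(c(0, 1))
  det <- mk(c(0.5, 0.5), z = c(0, 0), id = c(7L, 3L))
  m <- match_markers(gt, det, tol)
  a <- m$assignments
  expect_equal(a$det_id[a$gt_id == 1 & a$class == "TP"], 3L)  # tie -> low id
  expect_equal(m$n_tp, 2L)
})

test_that("count identities hold and frames must agree", {
  tol <- tolerance_spec(3, 1.5)
  for (s in 1:10) {
    cfg <- stereobench:::with_seed(400 + s, {
      n <- sample(3:40, 1)
      gt <- mk(runif(n, 0, 50), runif(n, 0, 50), runif(n, 0, 10))
      nd <- sample(0:40, 1)
      det <- mk(runif(nd, 0, 50), runif(nd, 0, 50), runif(nd, 0, 10))
      list(gt = gt, det = det)
    })
    m <- match_markers(cfg$gt, cfg$det, tol)
    expect_equal(m$n_tp + m$n_fn, m$n_gt)
    expect_equal(m$n_tp + m$n_fp, m$n_s)
    expect_true(all(c(m$r_tp, m$r_fp, m$r_tpi, m$r_tpb) >= 0))
    expect_true(all(c(m$r_tp, m$r_fp, m$r_tpi, m$r_tpb) <= 1))
  }
  g1 <- marker_set(1, 0, 0, 0, spacing = c(1, 1, 1))
  g2 <- marker_set(1, 0, 0, 0, spacing = c(0.5, 0.5, 1))
  expect_error(match_markers(g1, g2, tol), "coordinate frames")
})

test_that("matching is invariant under joint translation and monotone in tolerance", {
  cfg <- stereobench:::with_seed(31, {
    gt <- mk(runif(25, 0, 40), runif(25, 0, 40), runif(25, 0, 12))
    det <- mk(runif(30, 0, 40), runif(30, 0, 40), runif(30, 0, 12))
    list(gt = gt, det = det)
  })
  tol <- tolerance_spec(3, 1.5)
  m0 <- match_markers(cfg$gt, cfg$det, tol)
  sh <- function(m, dx, dy, dz) mk(m$x_um + dx, m$y_um + dy, m$z_um + dz,
                                   boundary = m$boundary, id = m$id)
  m1 <- match_markers(sh(cfg$gt, 5, -3, 2), sh(cfg$det, 5, -3, 2), tol)
  expect_equal(m1$n_tp, m0$n_tp)
  expect_equal(m1$assignments, m0$assignments)
  # shrinking the cylinder never gains true-positives
  tps <- vapply(list(tolerance_spec(4, 2), tolerance_spec(3, 1.5),
                     tolerance_spec(2, 1), tolerance_spec(1, 0.5)),
                function(tl) match_markers(cfg$gt, cfg$det, tl)$n_tp,
                numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("published-count examples reproduce their printed rates", {
  r <- detection_rates(153, 2, 1191, 155, 1344)
  expect_equal(format_rate(r[["r_tp"]]), "0.99")
  expect_equal(format_rate(r[["r_fp"]]), "0.89")
  r2 <- detection_rates(133, 22, 5, 155, 138)
  expect_equal(format_rate(r2[["r_fp"]]), "0.04")
  expect_equal(format_rate(r2[["r_fp"]], 3), "0.036")
  expect_equal(detection_rates(0, 5, 0, 5, 0, warn = FALSE)[["r_tp"]], 0)
  w <- capture_warnings(r0 <- detection_rates(0, 0, 0, 0, 0))
  expect_equal(unname(r0), c(0, 0))
  expect_match(w, "defined as 0", all = TRUE)
  expect_error(detection_rates(5, 1, 1, 7, 6), "identity")
})

test_that("stratified rates split by the boundary flag", {
  tol <- tolerance_spec(3, 1.5)
  gt <- mk(seq(0, 50, 10), boundary = c(0L, 0L, 0L, 1L, 1L, 1L))
  det <- mk(seq(0, 50, 10))                  # everything matched
  m <- match_markers(gt, det, tol)
  expect_equal(stratified_rates(m), c(r_tpi = 1, r_tpb = 1))
  expect_equal(m$r_tpi, m$r_tp)
  # only boundary cells detected
  det_b <- mk(seq(30, 50, 10), id = 1:3)
  mb <- match_markers(gt, det_b, tol)
  expect_equal(stratified_rates(mb), c(r_tpi = 0, r_tpb = 1))
  # all interior: boundary stratum empty
  gt_i <- mk(seq(0, 20, 10))
  mi <- match_markers(gt_i, mk(seq(0, 20, 10)), tol)
  expect_warning(sr <- stratified_rates(mi), "empty boundary")
  expect_equal(sr[["r_tpi"]], mi$r_tp)
  expect_equal(sr[["r_tpb"]], 0)
})

test_that("greedy never beats the optimal assignment", {
  skip_if_not_installed("igraph")
  tol <- tolerance_spec(3, 1.5)
  for (s in 1:15) {
    cfg <- stereobench:::with_seed(500 + s, {
      n <- sample(5:50, 1)
      gt <- mk(runif(n, 0, 40), runif(n, 0, 40), runif(n, 0, 10))
      det <- mk(gt$x_um + rnorm(n, 0, 2), gt$y_um + rnorm(n, 0, 2),
                gt$z_um + rnorm(n, 0, 1))
      list(gt = gt, det = det)
    })
    m <- match_markers(cfg$gt, cfg$det, tol)
    expect_lte(m$n_tp, oracle_optimal_tp(cfg$gt, cfg$det, tol))
  }
})

test_that("combination idempotence and set semantics", {
  tol <- tolerance_spec(3, 1.5)
  gt <- mk(c(0, 10, 20))
  mA <- match_markers(gt, mk(c(0.5, 10.5, 100, 110), id = 1:4), tol)
  expect_equal(mA$n_tp, 2L)
  expect_equal(mA$n_fp, 2L)
  u_self <- combine_union(mA, mA)
  expect_equal(c(u_self$n_tp, u_self$n_fp, u_self$n_s),
               c(mA$n_tp, mA$n_fp, mA$n_s))
  i_self <- combine_intersection(mA, mA)
  expect_equal(c(i_self$n_tp, i_self$n_fp), c(mA$n_tp, mA$n_fp))
  # A finds {1,2}, B finds {2,3}
  mB <- match_markers(gt, mk(c(10.4, 20.4), id = 1:2), tol)
  u <- combine_union(mA, mB)
  expect_equal(u$n_tp, 3L)
  expect_equal(u$n_fn, 0L)
  i <- combine_intersection(mA, mB)
  expect_equal(i$n_tp, 1L)                   # only gt 2 found by both
  # disjoint true-positive sets
  mC <- match_markers(gt, mk(0.2, id = 1L), tol)
  mD <- match_markers(gt, mk(20.2, id = 1L), tol)
  expect_equal(combine_intersection(mC, mD)$n_tp, 0L)
  # different ground truth is refused
  mE <- match_markers(mk(c(0, 10)), mk(0.1, id = 1L), tol)
  expect_error(combine_union(mA, mE), "different ground truth")
})

test_that("union FP dedup merges mutually-close false detections", {
  tol <- tolerance_spec(3, 1.5)
  gt <- mk(0)
  # both methods miss gt and produce one FP at nearly the same spot
  mA <- match_markers(gt, mk(50, id = 1L), tol)
  mB <- match_markers(gt, mk(50.5, id = 1L), tol)
  expect_equal(combine_union(mA, mB, dedup = TRUE)$n_fp, 1L)
  expect_equal(combine_union(mA, mB, dedup = FALSE)$n_fp, 2L)
  expect_equal(combine_intersection(mA, mB)$n_fp, 1L)
  # far-apart FPs never merge
  mC <- match_markers(gt, mk(80, id = 1L), tol)
  expect_equal(combine_union(mA, mC, dedup = TRUE)$n_fp, 2L)
  expect_equal(combine_intersection(mA, mC)$n_fp, 0L)
})

test_that("union/intersection bound the individual rates over random runs", {
  tol <- tolerance_spec(3, 1.5)
  for (s in 1:5) {
    cfg <- stereobench:::with_seed(700 + s, {
      n <- 30
      gt <- mk(runif(n, 0, 80), runif(n, 0, 80), runif(n, 0, 12))
      jitterset <- function(drop_p, fp_n) {
        keep <- runif(n) > drop_p
        mk(c(gt$x_um[keep] + rnorm(sum(keep), 0, 1), runif(fp_n, 100, 150)),
           c(gt$y_um[keep] + rnorm(sum(keep), 0, 1), runif(fp_n, 0, 80)),
           c(gt$z_um[keep] + rnorm(sum(keep), 0, 0.5), runif(fp_n, 0, 12)))
      }
      list(gt = gt, a = jitterset(0.2, 5), b = jitterset(0.3, 8))
    })
    mA <- match_markers(cfg$gt, cfg$a, tol)
    mB <- match_markers(cfg$gt, cfg$b, tol)
    u <- combine_union(mA, mB)
    i <- combine_intersection(mA, mB)
    expect_gte(u$r_tp, max(mA$r_tp, mB$r_tp))
    expect_gte(u$n_fp, max(mA$n_fp, mB$n_fp))
    expect_lte(i$r_tp, min(mA$r_tp, mB$r_tp))
    expect_lte(i$r_fp, min(mA$r_fp, mB$r_fp))
    for (m in list(u, i)) {
      expect_equal(m$n_tp + m$n_fn, m$n_gt)
      expect_equal(m$n_tp + m$n_fp, m$n_s)
    }
  }
})
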