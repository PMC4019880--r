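#!/usr/bin/env Rscript
# Combining two detector parameterizations: the union of detected objects
# raises the true-positive rate (and can only raise the false-positive
# count), while requiring agreement of both (intersection) lowers both
# rates. Twenty seeded replicates of a confocal-like condition with a wide
# cell-intensity range, so a permissive and a conservative threshold find
# genuinely different cell subsets.
library(stereobench)

dir.create("results", showWarnings = FALSE)

p <- scale_profile(preset_profiles()[["3B"]], 128, 128, 20)
tol <- tolerance_spec(3, 2)
pop <- cell_population(15, min_separation = 6,
                       intensity_range = c(0.35, 0.9))
detA <- detector_params(70, min_voxels = 25)    # permissive threshold
detB <- detector_params(140, min_voxels = 25)   # conservative threshold

rows <- do.call(rbind, lapply(1:20, function(s) {
  g <- generate_stack(p, pop, noise_model(), seed = 3000 + s)
  mA <- match_markers(g$markers, detect_cells(g$stack, detA)$markers, tol)
  mB <- match_markers(g$markers, detect_cells(g$stack, detB)$markers, tol)
  u <- combine_union(mA, mB)
  i <- combine_intersection(mA, mB)
  data.frame(seed = 3000 + s,
             rtp_A = mA$r_tp, rtp_B = mB$r_tp,
             rtp_union = u$r_tp, rtp_intersection = i$r_tp,
             nfp_A = mA$n_fp, nfp_B = mB$n_fp,
             nfp_union = u$n_fp, nfp_intersection = i$n_fp)
}))

write.csv(rows, "results/combination.csv", row.names = FALSE)
cat(sprintf("mean R_tp: permissive %.2f, conservative %.2f, union %.2f, intersection %.2f\n",
            mean(rows$rtp_A), mean(rows$rtp_B), mean(rows$rtp_union),
            mean(rows$rtp_intersection)))
cat(sprintf("union R_tp >= max(individual) in %d/20 runs\n",
            sum(rows$rtp_union >= pmax(rows$rtp_A, rows$rtp_B))))
cat(sprintf("intersection R_tp <= min(individual) in %d/20 runs\n",
            sum(rows$rtp_intersection <= pmin(rows$rtp_A, rows$rtp_B))))
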