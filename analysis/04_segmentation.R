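#!/usr/bin/env Rscript
# Stage 4 — metabolite-driven pixel segmentation.
#
# Per experiment: exact t-SNE on the z-scored consensus peak matrix (seeded
# subsample + nearest-neighbour placement), k-means (k = 2), automated
# cross-experiment cluster matching by signature correlation, Region-A
# fractions per tissue, recovery against ground truth (ARI), and the
# overlap between the full four-arm segmentation and a vehicle+drugA-only
# re-segmentation (the re-segmentation robustness check).

library(msipd)
suppressMessages(library(mclust))
if (!file.exists("results/front.rds"))
  stop("stage 'peaks' output missing: run analysis/02_peaks.R first")
front <- readRDS("results/front.rds")
cfg <- study_config(seed = 1)

segs <- segment_study(front$peak_matrix, segmentation_config(), "vehicle")
truth <- study_region_truth(cfg)
tt <- study_tissues(cfg)

aris <- vapply(1:3, function(e) {
  seg <- segs[[sprintf("Experiment-%d", e)]]
  rows <- tt[tt$e == e, ]
  tr <- unlist(lapply(rows$tissue_id, function(t) as.vector(truth[[t]])))
  pr <- unlist(lapply(rows$tissue_id, function(t) seg$region[seg$tissue_id == t]))
  adjustedRandIndex(pr, ifelse(tr == 1, "A", "B"))
}, numeric(1))
cat("ARI vs ground truth per experiment:", round(aris, 4), "\n")

fr <- do.call(rbind, lapply(segs, function(seg)
  do.call(rbind, lapply(unique(seg$tissue_id), function(tid)
    data.frame(experiment = seg$experiment_id[1],
               tissue_id = tid, arm = seg$arm[seg$tissue_id == tid][1],
               region_a_pct = region_fraction(seg, tid))))))
print(aggregate(region_a_pct ~ arm, fr, mean))

sel <- front$peak_matrix$pixels$arm %in% c("vehicle", "drugA")
pm_sub <- structure(list(intensity = front$peak_matrix$intensity[sel, ],
                         pixels = front$peak_matrix$pixels[sel, ],
                         peaks = front$peak_matrix$peaks),
                    class = "peak_matrix")
segs_sub <- segment_study(pm_sub, segmentation_config(), "vehicle")
ovl <- vapply(names(segs), function(e)
  segmentation_overlap(segs[[e]], segs_sub[[e]]), numeric(1))
cat("pixel-occupancy overlap, 4-arm vs 2-arm segmentation:",
    round(ovl, 2), "\n")

write.csv(fr, "results/region_fractions.csv", row.names = FALSE)
saveRDS(segs, "results/segmentations.rds")
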