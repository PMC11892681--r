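#!/usr/bin/env Rscript
# Stage 1 — simulate the study.
#
# Generates the default synthetic study (3 independent experiments x 4 arms
# x 2 tissues, 64x64 MSI grids at 50 um, 50-metabolite panel with a drug
# ion, region prevalences vehicle 0.8 / drugA 0.3 / drugB 0.5 / combo 0.1)
# and writes it to disk as imzML + landmark tables + IMC TIFFs for the
# final experiment, with ground truth alongside.
#
# The on-disk study is what a real analysis would start from; the later
# stages regenerate tissues in memory from the same seed (bit-identical)
# to avoid re-parsing XML at every step.

library(msipd)

out_dir <- file.path("results", "study")
cfg <- study_config(seed = 1)

st <- generate_study(cfg, out_dir, roi_um = 400)
cat(sprintf("wrote %d tissues to %s\n", nrow(st$manifest), out_dir))
print(head(st$manifest[, c("tissue_id", "experiment", "arm")]))

# sanity: the written files read back
d <- read_imzml(st$manifest$imzml[1])
cat(sprintf("read back %s: %d pixels, m/z %g-%g\n",
            d$tissue_id, nrow(d$coords), d$mass_range[1], d$mass_range[2]))
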