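# msipd — MSI-guided mapping of heterogeneous tumour pharmacodynamic response

`msipd` is an R implementation of a mass-spectrometry-imaging (MSI) based
workflow for measuring *where* in a tumour a pathway inhibitor acted, not
just whether it acted on average. It is written for computational
biologists working with spatial metabolomics (MALDI/DESI imzML data) who
want a tested, fully reproducible version of the following analysis chain:

1. **Spectral preprocessing** — imzML read/write, interpolation rebinning
   onto a uniform axis, per-pixel RMS normalisation
   (`x / sqrt(mean(x^2))`), experiment mean spectra.
2. **Peak pipeline** — gradient peak detection on the mean spectrum (apex
   where the first difference turns + → −, bounds at the flanking minima),
   per-pixel integration into ion images (display-clipped at the pooled
   95th percentile), accurate-mass adduct annotation with nested
   inclusion/accuracy ppm windows, and consensus matching that keeps only
   peaks common to **all** experiments.
3. **Response statistics** — per-tissue means; log2 fold change of each
   tissue against the mean of the *same experiment's* vehicle tissues, so
   batch scale factors cancel exactly:
   `FC_t = log2( x̄_t / mean(x̄_vehicle, same experiment) )`;
   two-sided Welch t-tests and two-way (arm + experiment, type-II) ANOVA
   at the tissue level; 1/25/50/75/99% boxplot summaries; a drug-ion
   report (e.g. AZD2014 [M+H]⁺ at m/z 463.2452).
4. **Segmentation** — per experiment, exact t-SNE on the z-scored
   consensus peak matrix followed by k-means (k = 2); clusters matched
   across experiments by signature correlation, with the vehicle-dominant
   family named Region A; Region-A fractions per tissue and
   pixel-occupancy overlap between segmentations.
5. **Cross-modal** — landmark least-squares affine registration of the MSI
   grid onto 1 µm imaging-mass-cytometry (IMC) images, label transfer,
   nuclear/cytoplasm cell segmentation with explicit size gates (nucleus
   20–571 µm², cytoplasm expansion ≤ 4 µm, cell ≤ 600 µm²), and per-region
   marker intensity / positive-cell statistics.
6. **Synthetic studies** — a seeded generator producing multi-batch
   MSI + IMC phantoms with full ground truth (latent two-region tissues,
   programmed region/treatment/batch effects, lognormal noise, a
   treated-arms-only drug ion, known affine to the IMC frame), so every
   stage of the pipeline has a recoverable answer.

The repository is organised as an analysis: the package under `R/` holds
all computation; the numbered scripts under `analysis/` are thin drivers
that run the study end to end and write tables under `results/`; the
methods vignette (`vignettes/msipd-methods.Rmd`) documents the models,
parameter choices and limitations.

## Worked example

```r
library(msipd)

# a compact study: 2 experiments x 2 arms x 2 tissues, 24x24 pixel grids
cfg <- study_config(
  n_experiments = 2, arms = c("vehicle", "drugA"), tissues_per_arm = 2,
  grid_shape = c(24, 24), region_prevalence = c(vehicle = 0.8, drugA = 0.3),
  metabolite_panel = default_metabolite_panel(c("vehicle", "drugA"), 30),
  seed = 42)

front <- study_peak_matrix(cfg)          # preprocess + detect + match + integrate
tm    <- tissue_means(front$peak_matrix)
fc    <- log2fc_vs_vehicle(tm, "vehicle")
drug  <- drug_ion_report(front$peak_matrix, tm,
                         adduct_mz(formula_mass("C25H30N6O3"), "[M+H]+"),
                         ppm = 150)
tests <- compare_arms(fc, "drugA", "vehicle")
segs  <- segment_study(front$peak_matrix,
                       segmentation_config(perplexity = 30), "vehicle")
```

Output printed by this example:

```
consensus peaks: 30
drug ion: m/z 463.2450 (-0.37 ppm), mean treated log2FC 8.14
significant peaks (P < 0.05): 30 of 30
mean vehicle Region-A fraction per experiment: 80 80 %
```

Reading it: all 30 panel metabolites were detected in both experiments and
matched into one consensus set; the drug ion was re-identified by accurate
mass to within 0.4 ppm and is ~2⁸ above vehicle background in treated
tissues (it is programmed 8 log2 units above background); with per-pixel
noise averaged over hundreds of pixels per tissue, every vehicle-normalised
endpoint separates the arms at P < 0.05; and the segmentation recovers the
programmed 80 % Region-A prevalence of the vehicle tissues.

The full-scale analysis (3 experiments × 4 arms, 64×64 grids, 50
metabolites) is driven by the numbered scripts:

```sh
cd analysis && Rscript 01_simulate.R && Rscript 02_peaks.R && \
  Rscript 03_response.R && Rscript 04_segmentation.R && \
  Rscript 05_crossmodal.R && Rscript 06_report.R
```

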