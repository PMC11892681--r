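---
title: "Methods: MSI-guided mapping of heterogeneous pharmacodynamic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI-guided mapping of heterogeneous pharmacodynamic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk pharmacodynamic biomarkers (western blots of pS6 or pAKT from tumour
lysates) report whether a pathway inhibitor hit its target on average, but
they cannot resolve *where* in a tumour the response occurred or whether
resistant subregions persist. Mass spectrometry imaging (MSI) measures a
full metabolite spectrum at every 50-60 µm pixel of a tissue section, so
treatment-induced metabolic change can be mapped, the tissue can be
segmented into metabolically distinct regions, and those regions can then
direct antibody-based imaging mass cytometry (IMC) at ~1 µm to ask which
protein markers distinguish responding from non-responding tissue.

`msipd` implements that workflow end to end — spectral preprocessing, peak
detection and annotation, cross-batch harmonisation, vehicle-normalised
fold-change statistics, metabolite-driven segmentation, and MSI→IMC
registration with per-region cell quantification — together with a seeded
synthetic study generator that provides full ground truth, so every stage
has a recoverable answer and the whole pipeline is testable.

## Spectral preprocessing

Per-pixel spectra are rebinned onto a uniform axis by linear interpolation
(value at each bin centre; zero outside the input support), RMS-normalised
(divided by `sqrt(mean(intensity^2))` over the full axis, zeros included),
and averaged into one mean spectrum per experiment. Two conventions are
fixed deliberately:

* **Axis**: half-open bins `[low + i·w, low + (i+1)·w)` anchored at the low
  end of the acquisition mass range, values carried at bin centres.
* **RMS per pixel, not per tissue**: whole-spectrum normalisation per pixel
  mitigates pixel-to-pixel ionisation variation; computing it over the full
  axis (zeros included) is stable for sparse centroid data, where a
  nonzero-only RMS would depend on peak count.

Internally coordinates are 0-based (x rightward, y downward); imzML
serialisation is 1-based per the standard. The imzML reader/writer is part
of the package (processed mode written; processed and continuous read;
float64 m/z, float32 intensities, UUID-linked `.ibd`), since no installed R
package provides imzML IO; the writer's output is cross-checked against an
independent Python parser in the test suite.

## Peak pipeline

Peaks are detected on the RMS-normalised experiment mean spectrum by a
gradient approach: apexes where the first difference turns from positive to
negative (plateaux from peaks falling exactly between bins are crossed),
bounds at the nearest positions where intensity stops decreasing, adjacent
windows sharing a minimum resolved in favour of the left peak. The reported
peak centre is the intensity-weighted centroid of the window, which restores
sub-bin (ppm-scale) mass accuracy on coarse axes. Detection uses a floor of
3× the median absolute deviation of the mean spectrum by default.

Annotation is accurate-mass only, with two nested ppm windows (an inclusion
window for candidate search and a tighter accuracy window for retention),
polarity-specific adducts ([M+H]⁺/[M+Na]⁺/[M+K]⁺ positive;
[M−H]⁻/[M+Cl]⁻ negative) and electron-corrected adduct mass shifts
(±1.007276 Da for protonation, etc.). Identification is therefore tentative
by mass, as in any database-lookup workflow without MS/MS.

Cross-experiment harmonisation keeps only peaks common to **all**
experiments: peak centres from all experiments are pooled, sorted, chained
into groups within a ppm tolerance (default 50 ppm; centroid-refined
centres make this comfortable), and a group is retained only when every
experiment contributes exactly one member. The consensus m/z is the
unweighted mean of the members, experiments being equal replicates.
Integration then uses each experiment's own member bounds.

## Response statistics

The statistical unit is the tissue, not the pixel. Per tissue we take the
mean integrated intensity of each consensus peak; per experiment we divide
by the mean over that experiment's vehicle tissues and take log2. Because
each experiment is normalised to its own vehicle arm, a global batch scale
factor multiplies numerator and denominator alike and cancels exactly —
this equivariance is what lets three separately acquired batches be pooled,
and it is asserted to 1e-9 in the tests. Between-arm comparisons use a
two-sided Welch t-test on per-tissue log2 fold changes pooled across
experiments (Student variant selectable), or a two-way ANOVA with additive
factors arm and experiment (type-II sums of squares; no interaction, given
the small per-cell n). No multiplicity correction is applied by default — raw P values are
reported per endpoint; Benjamini–Hochberg is available via
`p_adjust = "BH"`. Whether tests should
pool tissues across experiments is not dictated by the data model; pooling
is this package's default and recorded here as an assumption. Boxplot
summaries use interpolated quantiles with the box at 25/75% and whiskers at
1/99%, retaining per-tissue points tagged by experiment.

## Segmentation

Features are the RMS-normalised integrated consensus-peak intensities,
z-scored per peak within each experiment (preventing high-abundance ions
from dominating distances). Dimensionality reduction is an exact t-SNE
implemented in compiled code: perplexity-calibrated conditional
probabilities (bisection on the bandwidth; default perplexity 150 on a
2,000-pixel fit — a global-structure regime in which regions coalesce
rather than fragmenting into per-arm islands that k = 2 could not
reassemble), PCA initialisation (making the
embedding deterministic — no RNG in the optimiser), early exaggeration, and
delta-bar-delta gains. Exact t-SNE is quadratic in the fitted pixel count,
so the fit uses a seeded subsample (default 2,000 pixels) and the remaining
pixels are placed at the embedding coordinates of their nearest fitted
neighbour in feature space. Any embedding that preserves local
neighbourhoods and offers an out-of-sample map would be conformant here;
the biology-bearing output is the k-means partition, not the embedding
coordinates, and a `passthrough` mode (embedding = standardised features)
exists precisely so the clustering contract can be tested independently of
the embedding.

k-means uses k = 2 with ten restarts, each a Lloyd run on the embedding.
Restarts alternate k-means++ and seeded uniform-random initialisation: the
two families have different basins of attraction (k-means++ favours
extremal blobs), and the selection step needs to see both. The best restart
is selected by within-cluster sum of squares in the original z-scored
**feature** space rather than in the embedding: t-SNE equalises inter-blob
distances, so when pixels form several blobs (regions × arms) the embedding
inertia can prefer a treatment-arm split even though the metabolic-region
split is far tighter in feature space — evaluating candidates where
distances carry meaning removes that failure mode while keeping the
clustering itself on the embedding. Ties are broken by the lowest restart
index, so results are deterministic given the seed.

Clusters are matched across experiments automatically (replacing manual
matching): cluster signatures (mean intensity per consensus peak, z-scored
across clusters) are correlated between experiments, each experiment's
clusters are assigned to the first experiment's by maximal Pearson
correlation (a tie within 1e-9 is an error — more peaks are needed), and
the matched family holding the larger pixel share in vehicle tissues is
named Region A, the control-dominant region. Region fractions are reported
per tissue as percentages; the pixel-occupancy overlap between two
segmentations is the percentage of shared pixels (matched on tissue and
coordinates) with identical region labels — computed on shared retained
pixels, which is this package's recorded reading of that metric.

## Cross-modal registration and IMC quantification

Registration is landmark-based: an affine map from MSI µm-coordinates to
IMC µm-coordinates fitted by least squares on ≥ 3 non-collinear landmark
pairs. Landmarks make the contract exact and testable (a noiseless refit
recovers a known transform to < 1e-6 µm), where an intensity-based
registration would not be. Coordinate conventions are explicit to avoid
half-pixel drift: MSI pixels are squares of side `pitch` anchored at
`index × pitch`; IMC pixel centres sit at `(i + 0.5) × pitch`. Label
transfer maps each IMC pixel centre through the inverse affine, takes
`floor(coordinate / pitch)` as the MSI index, and inherits that pixel's
region; IMC pixels outside the MSI footprint are "unassigned".

Cell segmentation is a deliberately simple open model standing in for
proprietary software whose numeric gates are public: nuclei are connected
components of the thresholded DNA channel gated to 20-571 µm²; the cell
footprint is the nucleus expanded by at most 4 µm with contested pixels
split at the equidistant boundary between competing nuclei (per-nucleus
distance transforms), truncated farthest-first so cell area never exceeds
600 µm². Region statistics are emitted at both pixel level (mean marker
intensity over the region's pixels) and cell level (cells assigned by
nucleus centroid; a cell is positive for a marker iff its mean intensity
reaches that marker's threshold — thresholds are per-marker configuration,
as in practice they are tuned manually). Quantification is restricted to a
configurable field of view per tissue (IMC acquisitions cover ~2×2 mm
regions of interest).

## The synthetic study generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed once:

* 3 experiments (batches) × 4 arms (vehicle, drugA = mTORC1/2-inhibitor
  analogue, drugB = PI3Kβ-inhibitor analogue, combo) × 2 tissues, 64×64
  grids at 50 µm.
* Two latent regions per tissue from quantile-thresholded smoothed Gaussian
  noise (smoothing sd 6 px) — spatially coherent regions without modelling
  histology — with expected Region-A prevalence vehicle 0.8, drugA 0.3,
  drugB 0.5, combo 0.1, realised exactly up to one-pixel quantisation.
* A 50-metabolite panel: six Region-A-high ions (+2 log2, the ATP-like
  signature), six Region-B-high (−2 log2), six treatment-suppressed and six
  treatment-induced ions (±1.0 / ±0.6 / ±1.6 log2 for drugA / drugB /
  combo, applied tissue-wide), the rest inert high-abundance ions, plus a
  drug ion (neutral mass 462.2379 Da, [M+H]⁺ 463.2452) present at an
  8-log2-lower background in vehicle tissues and spatially uniform in
  treated ones. Region-defining and treatment-responding sets are disjoint:
  a metabolite carrying both effects would have a tissue-mean fold change
  confounded by the arm-dependent region prevalence, and the recovery
  contract (estimated mean log2FC = programmed effect) could not hold.
* Batch log2 offsets of 0 / +0.6 / −0.4 across experiments and
  multiplicative lognormal noise with CV 0.2, parameterised median-one
  (`exp(σZ)`, `σ² = log(1+cv²)`) so the programmed value is recovered both
  as the mean log2 intensity and — because the lognormal mean factor
  cancels in the vehicle ratio — as the fold change. m/z jitter is 5 ppm
  per peak per pixel.
* Spectra are emitted in profile mode by default: each peak is a sampled
  Gaussian (sd 0.08 Da) with explicit zero baseline anchors. Interpolation
  rebinning of bare centroid sticks would draw monotone ramps between
  peaks, which breaks gradient bound detection; profile rendering matches
  how Orbitrap DESI data are actually acquired. A stick mode remains for
  closed-form tests.
* IMC phantoms: disk nuclei (radius 3-5.5 µm, giving areas well inside the
  20-571 µm² gates) placed without overlap at 600 cells/mm², marker values
  painted inside cell footprints on a normalised 0-1 intensity scale, and a
  known mild affine (rotation ≤ 4°, scale 0.97-1.03) tying the IMC field to
  the MSI grid. Marker rules encode the regional response pattern: pS6
  suppressed equally in both regions under treatment; GLUT1 and Ki67
  suppressed in Region B but retained in Region A; CD31 and collagen I
  differing between regions independently of treatment.

Every tissue's RNG stream derives from the master seed by a stable string
hash, so generation order cannot affect reproducibility, and identical
configuration and seed give bit-identical studies.

**What the phantom does not emulate**: real histology and vasculature,
isotope envelopes and adduct competition, matrix/ablation artefacts,
section-to-section registration error, cell shapes beyond disks, antibody
noise structure. Passing tests therefore demonstrate that the algorithms
recover what they are specified to recover under controlled conditions —
not that annotations or segmentations of real tissue would be correct.

## Numerical choices and problem sizes

Desk-scale analyses in this repository use a 0.05 Da rebin width with
0.08 Da peak widths (the 0.001 Da width of high-resolution Orbitrap
workflows applies to real profile data; at 0.05 Da the full default study
is ~19k bins × 98k pixels) and a 2,000-pixel t-SNE fit subsample — exact
t-SNE is quadratic, so this is the knob that keeps the embedding minutes,
not hours; the nearest-neighbour out-of-sample map places the remaining
~30k pixels per experiment. Peak-centre centroid refinement keeps
annotation meaningful at that bin width (sub-ppm on synthetic data).
Degenerate inputs are contracts, not surprises: all-zero pixels are
excluded from normalisation and flagged; an empty consensus set stops the
pipeline; a segmentation with unmatched clusters refuses region arithmetic;
a DNA threshold yielding zero nuclei warns and returns an empty cell table.

## Known limitations

Accurate-mass annotation cannot distinguish isomers and is only as good as
the database and ppm windows. The automated cluster matching assumes k = 2
per experiment (the design of this workflow); matching more clusters would
need an assignment solver. The t-SNE is exact (no Barnes-Hut), so fit
subsamples beyond ~5,000 pixels become slow. The cell model ignores
membrane markers and non-convex cells. Statistical power at the tissue
level is what the design gives (n = 6 per arm pooled across batches in the
default study); the package reports raw P values and leaves correction to
the analyst.
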