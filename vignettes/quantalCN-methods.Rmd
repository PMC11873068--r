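---
title: "quantalCN: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quantalCN: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

quantalCN quantifies mitochondrial DNA copy number (mCN) per cell two ways -
image-based, from anti-dsDNA immunofluorescence puncta, and absolute, from
duplex droplet digital PCR - and implements the cytometry used around those
estimates in high-content studies of smooth muscle cells: nuclear
segmentation with Voronoi expansion, DNA-content ploidy gating, transfection
gating on a nuclear GFP reporter, TMRM/MitoSOX dye normalization,
growth-curve fitting and Mito-Stress-Test respiration metrics. A seeded
synthetic-data generator reproduces the statistical structure of each assay
with full ground truth, so every estimator in the package is tested by
parameter recovery.

# The quantal model of punctum intensity

Nucleoids packaging a single mtDNA copy dominate anti-dsDNA puncta, and a
punctum carrying $k$ copies has $k$ times the integrated fluorescence of a
single-copy nucleoid. The integrated intensity distribution is therefore
modelled as a constrained Gaussian mixture with component means $k q$,
$k = 1 \ldots 10$, where $q$ is the quantal (single-copy) intensity:

$$p(x) = \sum_{k=1}^{10} w_k\, \mathcal N\!\left(x;\; k q,\; \sigma^2 k\right).$$

The component variance grows linearly in $k$ (noise adds over quanta); this
costs a single parameter $\sigma$ and matches how the generator draws
punctum intensities. A cell's mCN estimate is its summed punctum intensity
divided by $\hat q$, real-valued and unrounded.

`fitQuantalMixture()` fits $(q, \sigma, w)$ by weighted least squares on the
intensity histogram (Freedman-Diaconis bin width, Poisson weights
$1/\max(n_i, 1)$). Two numerical points matter:

* **Exact bin integrals.** Expected bin counts are computed as
  $n\,[\Phi(b_{i+1}) - \Phi(b_i)]$ per component, not as a midpoint density
  times the bin width. With heavy-tailed samples the Freedman-Diaconis width
  can exceed $\sigma$, and the midpoint approximation is then biased enough
  to let spurious optima win.
* **Weights as predicted mass.** At fixed $(q, \sigma)$ the non-negative
  component amplitudes are solved exactly (NNLS); reported weights are each
  component's share of the *predicted count mass*, so a component placed
  outside the histogram support (a near-zero design column whose amplitude
  is unidentifiable) correctly receives zero weight.

The fit is multi-started on 20 log-spaced values of $q$ between the 5th
percentile and the histogram mode. The mixture has an exact aliasing
degeneracy - $q/2$ with mass on even components fits any histogram as well
as $q$ - which is resolved by the acceptance rule that the single-copy
component must be the most abundant: among the multi-start solutions the
best *admissible* one is returned, and if none is admissible the fit is
flagged invalid and downstream mCN estimation refuses to run. A raw-sample
EM with the same mean constraint (`method = "em"`) is provided and agrees
with the histogram fit within a few percent in tests.

# Segmentation conventions

* **Rolling background.** `subtractBackground()` implements the rolling-ball
  as grayscale opening with a disc, default radius 75 um (1.5 times the
  ~50 um largest expected nuclear diameter of A7r5 cells). The background is
  estimated on a lightly presmoothed copy (Gaussian, 2 px): a min-filter
  ridden over raw pixel noise tracks the noise's lower envelope and would
  leave a positive pedestal everywhere after subtraction. For radii above
  100 px the opening runs on a block-minimum shrunken image and is enlarged
  bilinearly (the standard large-radius acceleration); the estimate is
  capped at the image so output is non-negative.
* **Nuclei.** A single explicit intensity threshold per staining batch
  (an Otsu suggestion is available via `suggestThreshold()` but never
  applied silently), 8-connected components, area-filtered. Coordinates are
  0-based pixel centres; areas are $\text{px} \times (\text{um/px})^2$.
* **Voronoi territories.** Every pixel joins the nucleus whose *mask* is
  nearest (Euclidean, to the nuclear edge, not the centroid), capped at
  `floor(133 um / pixel size)` pixels, ties to the lower label. The
  cytosolic map excludes pixels within 4 px (default) of any nuclear mask.
  The kernel is exact and is tested against an $O(\text{pixels} \times
  \text{nuclei})$ brute-force oracle; shrinking the cap can only shrink
  territories (tested monotonicity).

# Punctum detection and integration

Local maxima above `peakMin` are found in a Chebyshev window of half-width
`minSeparationPx` (default 2) on a Gaussian-smoothed copy of the image
(sigma 1 px) - smoothing suppresses single-pixel noise maxima by a factor
of ~4 in noise amplitude; plateau ties go to the first pixel in (row,
column) order. Intensities are always integrated on the unsmoothed image
over a fixed $(2r+1)^2$ patch (default $r = 2$); the fixed patch keeps the
intensity distribution unit-additive, which the quantal fit relies on. The
median of the square ring just outside the patch is subtracted per patch
pixel: in crowded fields the overlapping tails of neighbouring puncta raise
a local pedestal of order the patch area times the local spot density, and
the ring median removes it while leaving the quantal spacing intact (the
punctum's own tail contributes proportionally to $k$, so the correction
rescales rather than distorts the quantal ladder).

Detection in dense scenes is imperfect - nearby puncta merge. Merging is
benign for the quantal analysis by construction: two merged single-copy
puncta read as one two-copy punctum, which the mixture model accommodates,
and per-cell summed intensity is approximately conserved. Accuracy
statements are therefore of two kinds: absolute mCN recovery is tested on
resolvable scenes, and between-condition contrasts (the assay's endpoint)
are tested at realistic density, where detection losses cancel in the
ratio to the reference condition.

# Gating

**Ploidy.** Cells are gated on integrated nuclear-stain intensity (and
nuclear area bounds) relative to the diploid G0/G1 modal intensity $m$:
2N $[0.75, 1.25)m$, 4N $[1.5, 2.5)m$, 8N $[3, 5)m$, with S-phase gates
filling the gaps. Manual gates are first class (the study gated by hand);
`autoGatesFromG1Peak()` exists to make analyses reproducible and locates
$m$ as the lowest kernel-density mode reaching 25% of the tallest peak.
Intervals are half-open so gates are disjoint by construction; boundaries
scale linearly under global intensity rescaling because $m$ does.

**Transfection.** Nuclear GFP intensities are fitted with an unconstrained
three-component Gaussian mixture (EM, k-means++ initialization, 10 seeded
restarts, tolerance 1e-8, components sorted by mean). Cells above
$\mu_1 + 3\sigma_1$ - three standard deviations over the untransfected
background component - are called transfected. The package's own EM is used
because generic hierarchical initialization demonstrably lands in a wrong
local optimum on exactly this kind of skewed mixture (a 75% background
component next to broad minority components); tests assert our solution's
log-likelihood is at least that of an independent reference implementation.

# Dye physiology

TMRM is normalized per plate to the pharmacological window:
$(I - \bar I_\mathrm{FCCP}) / (\bar I_\mathrm{oligo} - \bar I_\mathrm{FCCP})$,
which is exactly affine-invariant and may legitimately leave $[0, 1]$.
MitoSOX (measured in nuclear ROIs, where the dye concentrates at 5 uM) is a
plain ratio to the reference-population mean. Mitochondrial "mass" is the
supra-floor area per cytosolic ROI in um^2; sub-floor pixels are ignored,
never counted as zero, and an all-ignored ROI reports missing.

# ddPCR

Droplets are gated into the four duplex populations by two per-channel
thresholds - manual, or automatic as the midpoint between the two 1-D
cluster centres (2-means with deterministic decile initialization; a
channel whose centres sit closer than four within-cluster standard
deviations is flagged as not bimodal, since splitting a unimodal
distribution yields centres only ~1.6 within-sds apart). Target
concentrations use the Poisson void probability
$\lambda = -\ln(n_\mathrm{neg}/n)$; saturated wells return a lower bound,
not an estimate. Copies per cell are
$\lambda_\mathrm{ND1} / (\lambda_\mathrm{ACTB} / \text{loci per cell})$;
the default of 6 reference loci per cell (3 amplified loci per haploid
genome, diploid nuclei) scales the result directly and is exposed
prominently. Droplet volume cancels in the ratio, so no copies/uL output
is offered.

# Growth kinetics

`fitGrowth()` fits $c + a e^{kt}$ (the "3-parameter exponential" read as an
additive offset, the most common interpretation; the pure 2-parameter model
is also exposed) by Levenberg-Marquardt with Poisson-motivated $1/y$
weights - the observations are counts, and unweighted least squares lets
the high-count tail dominate. The rate is initialized by log-linear
regression on the upper half of the series. Doubling time is $\ln 2 / k$,
reported as missing (with the sign flagged) when $k \le 0$. With
`model = "auto"` both models are fitted and BIC chooses: when a series
spans roughly one doubling the additive offset is not identifiable and the
criterion falls back to the pure exponential instead of reporting an
offset-inflated rate. Rebasing a curve at the media-change time and
relative growth (final/first frame) are simple, tested conveniences.

# Respiration metrics

From a four-phase Mito-Stress trace (basal, oligomycin, FCCP,
rotenone/antimycin-A; at least three measurements per phase at 3-minute
increments) the vendor's point rules are used: non-mitochondrial OCR is the
post-rotenone/antimycin mean; ATP-linked is last-basal minus
minimum-post-oligomycin; proton leak is minimum-post-oligomycin minus
non-mitochondrial; basal is computed as their sum so the identity
basal = ATP-linked + proton leak is exact to the last bit; maximal is
maximum-post-FCCP minus non-mitochondrial. A maximal response below basal -
reported for this cell type at 1 uM FCCP - is still computed and flagged
rather than suppressed. Per-cell normalization divides by the imaged
nuclear count.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions: 1.24 um/px sampling, a mixed-ploidy population (2N-heavy, 8%
CV on integrated stain intensity, intensity exactly proportional to genome
copies with S-phase cells spanning their interval), 400 mtDNA copies per
cell on average (negative binomial, CV 0.2), per-punctum copy numbers
geometric-like with mode 1 over 1..10, quantal intensity 100 a.u. with
unit noise 8 a.u. scaling as $\sqrt k$, 25% transfected mass with GFP
components (100, 20, 0.75), (500, 80, 0.15), (2000, 300, 0.10), Gaussian
read noise, and a point spread of 1.5 px by default. Puncta are placed in
cytosolic annuli and never inside nuclei (the DNA stain is not visible in
mitochondria); per-cell copy totals are partitioned into puncta exactly,
so ground-truth conservation is testable to the integer.

Cells sit on a jittered grid, which guarantees non-overlapping nuclei or
fails loudly (no silent overlap); an explicit field size that cannot hold
the requested cells is an overcrowding error. For mCN quantification runs
the package uses 0.5 um/px sampling with a 1 px point spread - the
end-point imaging of this assay is done at 20x magnification (2x2-binned
sCMOS), where nucleoids are resolvable; at 10x IncuCyte sampling several
hundred puncta per cell are not individually separable by any detector.

Two conditions compared in an experiment are generated from the *same*
master seed (common random numbers): all draws go through inverse-CDF
transforms, so the reference and variant fields share cell layout and
copy-number quantiles and differ only in the configured means, and two
droplet conditions share their nuclear-reference occupancy stream. This is
the standard paired-simulation design for between-condition contrasts; it
mirrors the study's within-plate normalization to the wild-type condition
and removes layout and sampling noise from the contrast while leaving each
condition's marginal distribution untouched.

What the generator does **not** emulate: optical vignetting and chromatic
shifts, autofluorescence structure, cell shapes other than disks, nucleoid
clustering along mitochondrial networks, transfection biology or any
diffusible-factor kinetics (effect sizes are injected as parameters), and
ddPCR "rain" (partial-amplitude droplets). Passing recovery tests
therefore demonstrates correctness of the estimators under the assay's
statistical model, not robustness to every real-world artefact.

# Problem sizes and seeds

The recovery suites use the sizes at which the corresponding statements
are made: two 200-cell fields for the image-based contrast, 10,000 GFP
intensities, 20,000 droplets per condition, 20-minute sampling over
72 h/46 h growth windows, 600-cell gating fields, 500 cells per dye
condition, 5,000 puncta for the $(q, \sigma)$ recovery grid. Every source
of randomness derives from one master seed through fixed child streams;
the same configuration is bit-identical across runs, which the suite
asserts.

# Known limitations

* Image-based mCN is accurate in relative terms at realistic density;
  absolute accuracy requires resolvable scenes (higher magnification or
  lower copy load). This mirrors the assay itself, which reports mCN
  normalized to the wild-type condition per plate and anchors absolute
  numbers with ddPCR.
* The ddPCR per-cell figure inherits the assumption of diploid nuclei
  through `lociPerCell`; polyploid subpopulations deflate it
  proportionally. The parameter is exposed rather than corrected.
* The 4N ploidy gate cannot distinguish tetraploid G0/G1 from diploid
  G2/M; the class labels deliberately retain this ambiguity.
* `fitQuantalMixture()` reports no uncertainty on $\hat q$; plate-to-plate
  variation should be handled by fitting per batch (the default batch key
  is the plate).
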