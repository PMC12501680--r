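---
title: "The diffusion instability measure: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diffusion instability measure: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimqa)
```

## The measurement problem

Diffusion MRI is acutely sensitive to scanner instabilities — eddy currents,
RF transmit fluctuation, changing EPI ghost levels, parallel-imaging
reconstruction errors — and those instabilities grow with b-value and
sequence duration. Routine quality assurance needs a single quantitative
number that summarizes shot-to-shot image instability across a HARDI
acquisition, without special pulse sequences or reconstruction access.

The trick is the phantom: a sphere filled with silicone oil has practically
no diffusion (apparent diffusivity on the order of $10^{-6}$ mm$^2$/s), so
every diffusion-weighted volume should be an essentially identical copy of
the unweighted $b_0$ image, at any b-value up to at least
10 000 s/mm$^2$. The HARDI series can then be treated exactly like an fMRI
time series of a stationary object, and any decorrelation between volumes
is instability, not physiology.

## The statistic

Let $X \in \mathbb{R}^{N_v \times N_d}$ hold the $N_v$ masked phantom
voxels of each of the $N_d$ diffusion-weighted volumes, one volume per
column. Each column is centered with its own mean and rescaled, giving
$\hat X$, and

$$C = \hat X^{\mathsf T} \hat X \in \mathbb{R}^{N_d \times N_d}$$

is the matrix of Pearson correlation coefficients between
diffusion-encoding directions. With eigenvalues $\lambda_1 \ge \dots \ge
\lambda_{N_d}$ of $C$, the diffusion instability measure is

$$\mathrm{DIM} = 1 - \frac{\max_i \lambda_i}{\sum_i \lambda_i},$$

reported in parts per million (ppm). If all DWIs were perfect copies of one
another, $C$ would be the all-ones matrix of rank one and DIM would be
zero; for mutually uncorrelated volumes $C$ approaches the identity and DIM
its ceiling $1 - 1/N_d$. Useful data sit close to zero, hence the ppm
scale, and cross-dataset displays use a natural-log axis.

Two numerical notes:

* **Normalization constant.** Dividing a centered column by its standard
  deviation makes $\hat X^{\mathsf T}\hat X$ have diagonal $N_v$ (or
  $N_v - 1$); for $C$ to literally contain correlation coefficients the
  columns must have unit Euclidean norm. `standardizeColumns()` does the
  latter. The distinction is cosmetic for DIM itself — the eigenratio is
  invariant to any global scaling of $C$ — but it makes the stored matrix
  entries true correlations.
* **Eigen-solver.** The spectrum comes from a symmetric eigendecomposition
  of the tiny $N_d \times N_d$ matrix $C$, never from an SVD of the large
  $\hat X$; the SVD route exists in the test suite as an independent
  cross-check. The eigenvalue sum equals the trace $N_d$ exactly, and the
  spectrum of any valid correlation matrix is nonnegative, so
  $0 \le \mathrm{DIM} \le 1 - 1/N_d$.

DIM deliberately attributes nothing: it flags that volumes decorrelate,
not why. It also has no universal pass/fail threshold; it is meant for
tracking one scanner over time and comparing acquisition variants under
identical processing.

### Properties the implementation guarantees

* Invariance to voxel order, direction order, and any per-volume positive
  affine intensity transform (gain and offset).
* For i.i.d. noise columns, DIM approaches the ceiling $1 - 1/N_d$ from
  below as $N_v$ grows; the gap is governed by the largest-eigenvalue edge
  $(1 + \sqrt{N_d/N_v})^2$ of the sample correlation spectrum.
* Agreement with a brute-force pipeline (explicit pairwise Pearson loop
  plus dense eigendecomposition) to $10^{-10}$ relative.

## Pipeline around the statistic

**Masking.** The volume of interest should cover almost the entire
phantom. `makePhantomMask()` thresholds the $b_0$ volume at a fraction
(default 0.5) of the in-phantom mean intensity, keeps the largest
6-connected component, and fills interior holes. The in-phantom mean is
estimated in two passes — the mean of voxels brighter than half the 99.9th
intensity percentile — because on magnitude images the background is
positive noise, and a naive mean over all positive voxels would drag the
threshold down and bloat the mask outward into the partial-volume shell;
the percentile guard likewise keeps a stray hot voxel from pushing it up.
The recipe is scale invariant. Voxels enter the matrix in a fixed scan
order (x fastest, then y, then z); DIM is row-permutation invariant, so
the order only pins down reproducibility of intermediate objects.

**b0 handling.** Volumes with $b < 50$ s/mm$^2$ count as $b_0$ (vendor
tables sometimes store small nonzero values) and are excluded from $C$ by
default — the instability of interest lives among the DWIs — with
`includeB0 = TRUE` as the override. Direction-subset policies
(`all`, `exclude_first`, `exclude_last`, `custom`) support the standard
diagnostic of recomputing DIM without a suspect volume while keeping the
direction count comparable.

**Registration.** `estimateShifts()`/`applyShifts()` implement slice-wise,
translation-only registration of every volume to the first EPI volume:
per slice, 2D phase correlation (normalized cross-power spectrum) locates
the integer shift, and a matrix-multiply upsampled DFT evaluation of the
correlation surface around that peak refines it to 1/20 voxel. Shifts are
capped at 5 voxels to reject pathological matches on heavily ghosted
slices, and all-zero slices register to zero shift. Resampling is bilinear
with zero fill outside the field of view — consistent with the
translation-only model and free of ringing on a compact phantom; slices
with exactly zero shift (including the whole reference volume) pass
through bitwise. On drifting data, registration removes the spurious
decorrelation and consistently lowers DIM; the package asserts the
ordering, not a specific magnitude, because the registered value depends
on the interpolation scheme.

**Stability to mask size.** `voxelSubsamplingCurve()` removes random voxel
subsets (defaults: 1, 2, 3, 5, 10, 20 % — re-drawn independently for each
of 100 resamples) and recomputes DIM, re-standardizing the columns on each
subsample since their means and norms change. Each (fraction, resample)
cell draws from its own deterministic sub-seed, so curves are bitwise
reproducible regardless of evaluation order. At $N_v \sim 10^5$ the mean
curve stays within a fraction of a percent of the full-mask value even at
20 % removal — DIM is insensitive to the precise mask.

**Diffusivity check.** `estimateDiffusivity()` verifies the
near-zero-diffusion premise inside an 11×11×11 voxel cube at the mask
centroid: $D_i = -\tfrac{1}{b}\ln(\bar S_i / \bar S_0)$ per direction,
with multiple $b_0$ volumes averaged first. The logarithm is natural,
matching the exponential signal model $S = S_0 e^{-bD}$. The estimate is
scale invariant; the ROI mean over ~1300 voxels keeps the log's noise
amplification in check. A silicone-oil phantom should report a mean on
the order of $10^{-6}$ mm$^2$/s.

## The synthetic phantom

`simulationConfig()`/`generatePhantom()` render the study object: a
uniform sphere of configurable radius and base intensity on a dark
background, one $b_0$ volume plus $N_d$ DWIs attenuated by $e^{-bD}$,
with a deterministic Fibonacci-spiral direction set over the upper
hemisphere starting at the apex (seed-independent, so the gradient table
is reproducible by construction). Defaults: 96×96×48 grid, radius 26
voxels, 64 directions, $b = 1000$ s/mm$^2$, $D = 10^{-6}$ mm$^2$/s,
noiseless.

Geometry choices worth stating:

* The sphere edge carries a one-voxel linear partial-volume ramp. A hard
  binary edge would make every masked column exactly constant in the
  noiseless case — a degenerate correlation — whereas any discretized real
  phantom has partial-volume boundary voxels.
* The sphere must fit the in-plane FOV but may be truncated by the slice
  stack, and by default spans more than half the phase-encode matrix.
  Both mirror a real acquisition (a 17 cm sphere inside a ~13–22 cm
  imaging FOV, with the slice stack not necessarily covering the pole),
  and the second is load-bearing: an EPI Nyquist ghost displaced by half
  the FOV can only overlap — and therefore decorrelate — the phantom if
  the phantom is wider than half the phase-encode FOV.

Instabilities are applied per DWI volume $i$ in a fixed, documented order
(reproducibility outranks physical ordering realism):

1. **Intensity drift**: multiplicative factor $(1 + \delta)^i$,
   emulating RF/receiver drift.
2. **Positional drift**: in-plane translation by `shiftPerVolume`
   $\times\, i$ voxels (Fourier-exact subvoxel translation via the same
   bilinear resampler the registration uses).
3. **Half-FOV ghost**: each slice receives an additive copy of itself
   displaced by half the matrix along the phase-encode (second) axis,
   scaled by the direction's ghost amplitude — the canonical EPI Nyquist
   ghost geometry. `corruptDirections` adds a heavy ghost
   (`corruptAmplitude`, default 0.3) to selected volumes to emulate a
   single corrupted DWI.
4. **Noise**: i.i.d. Gaussian with SD `baseIntensity / snr` (the
   simulation-study convention); a Rician option
   (`noiseModel = "rician"`) exists for magnitude-image realism but is
   off by default.

The $b_0$ volume receives noise only. Identical config and seed give a
bitwise identical dataset.

What the generator does *not* emulate — and what passing tests therefore
do not certify on real scans: k-space/EPI trajectory physics, coil-array
and parallel-imaging artifacts, eddy-current geometric distortion,
through-plane motion, field drift with spatial structure, and temperature
dependence of the oil. The simulator produces the *kinds* of instability
DIM is sensitive to, with known ground truth, which is what the test
suite needs.

## The simulation study

`runSnrStudy()` sweeps DIM over a (b-value, diffusivity, SNR) grid with
noise as the only instability: defaults $D \in \{0, 10^{-7}, 10^{-6},
10^{-5}\}$ mm$^2$/s, SNR $\in \{200, 100, 50, 20\}$, and the acquisition
b-value ladder 500–10 000 s/mm$^2$. Expected behavior, which the
acceptance suite asserts: DIM rises monotonically as SNR falls, rises
with the attenuation $bD$ (less signal at fixed noise), and is flat
between $D = 0$ and $D = 10^{-7}$ — very low diffusion is invisible,
which is exactly why high-b QA on silicone oil works.

Cells sharing a (b, SNR) pair share one noise stream across the $D$ grid
(common random numbers). The diffusivity effect at $D \le 10^{-7}$ is a
fraction of a percent of DIM — far below across-seed scatter — and
pairing the noise isolates it; this mirrors deriving all $D$ variants
from a single measured $b_0$ volume before adding noise. Across SNR
levels, streams are independent: there the effect is a factor of ~4 per
halving and needs no pairing.

The study grid runs on a reduced phantom (48×48×32 grid, radius 14,
32 directions, $N_v \approx 10^4$) — the orderings under study are
N_v-insensitive (that is precisely the stability result), and the sweep
stays fast. The voxel-removal analysis, whose claim *is* about scale,
runs at $N_v \approx 10^5$ with the full 100 resamples.

## Degenerate inputs and tie-breaking

* Columns with zero variance (a constant volume inside the mask) are a
  hard error naming the offending direction; correlation is undefined.
* $N_d = 2$ is allowed (DIM $= (1 - r)/2$); $N_d = 1$ is rejected.
* Ties for $\lambda_{\max}$ need no tie-break — only the max value enters.
* Off-diagonal entries are clipped to $[-1, 1]$ and the diagonal pinned
  to 1 to absorb last-bit float asymmetry before the (validity-checked)
  correlation matrix is built.
* An empty mask after thresholding, an ROI escaping the mask, and
  nonpositive ROI mean signals are all hard errors rather than silent
  degradation.

## Reporting conventions

Correlation-matrix heatmaps default to the display window $[0.95, 1]$
(alternate $[0.7, 1]$ for visibly unstable data); clipping into the
window keeps structure near 1 visible. Cross-dataset DIM scatters use a
natural-log axis. Difference-image mosaics tile all slices of
$\text{volume}_i - \text{volume}_j$ with a symmetric gray window around
zero, the standard way to see a changing ghost. JSON is the primary
machine-readable result form; every command echoes $N_v$, $N_d$, the
subset policy and the eigenvalue extremes to its log so QA records are
self-describing.

## Worked example

```{r example, eval = FALSE}
library(dimqa)

# a clean scan and one with a heavily ghost-corrupted first direction
clean <- generatePhantom(simulationConfig(snr = 100, seed = 1))
bad <- generatePhantom(simulationConfig(snr = 100, corruptDirections = 1,
                                        corruptAmplitude = 0.5, seed = 1))

mask <- makePhantomMask(bad)
dimFromDataset(bad, mask = mask, subsetPolicy = "all")
dimFromDataset(bad, mask = mask, subsetPolicy = "exclude_first")
```

The corrupted scan's DIM falls back to the clean-scan level once the bad
volume is excluded (27 907 → 20 332 ppm at these settings, against a
clean-scan value of 20 337 ppm), while a clean scan's `exclude_first`
and `exclude_last` values agree to within a few percent — the package's
acceptance script (`scripts/acceptance.R`) recomputes exactly these
contrasts, plus the closed-form, oracle, stability, simulation-grid,
registration and diffusivity quantities, from scratch at every run.

## Known limitations

* DIM is a summary measure: it quantifies instability without localizing
  or attributing it.
* The registered DIM value depends on the interpolation scheme; only
  comparisons under identical processing are meaningful.
* The mask recipe is a default, not a reproduction of any particular
  scanner's VOI; DIM's insensitivity to mask size (the subsampling
  curve) is what makes that acceptable.
* Gaussian noise is the default even though magnitude MRI noise is
  Rician; at the SNR levels of interest (≥ 20 inside the phantom) the
  difference is negligible for DIM, and the Rician flag exists for
  checking exactly that.
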