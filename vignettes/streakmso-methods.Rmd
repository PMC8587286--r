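---
title: "Denoising FBP streak artifacts with structuring-element search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising FBP streak artifacts with structuring-element search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streakmso)
```

## The model

Filtered back-projection reconstructs a slice from its parallel-beam
projections by ramp-filtering each projection and smearing it back
across the image at its acquisition angle. When the number of angles is
small relative to the grid and the projections carry Poisson counting
noise, the unmatched high-frequency content back-projects into radial
*streaks* that raise the variance of the image background without
carrying signal.

`streakmso` treats streak removal as a discrete model-selection
problem. The candidate denoisers are binary masks
$A = (a_k)$, $a_k \in \{0, 1\}$, of shape $r \times c$ (2D) or
$r \times c \times s$ (3D) with every dimension at most 3. In the
default *masked local mean* mode the mask acts as a normalized
convolution kernel,

$$ B(x) \;=\; \frac{1}{p} \sum_{k:\,a_k = 1} X(x - k + a),
   \qquad p = \sum_k a_k, $$

with $a$ the anchor offset. Division by the popcount $p$ keeps the
intensity scale of the image: an un-normalized 0/1 convolution would
multiply the mean by $p$ and make contrast and SNR comparisons between
mask sizes meaningless. Because *morphological structure operator*
classically denotes an opening, the grayscale opening
(erosion-then-dilation with $A$ as a flat structuring element) is
retained as an explicit `mode = "opening"`; which reading a given
dataset deserves is a user decision, so both sit behind the same
interface and the choice is a flag in the pipeline configuration and
CLI.

The selection criterion is the **mean background standard deviation**:
for a designated streak-bearing background region, the population
standard deviation of background voxels is computed per slice and
averaged over slices. Lower is better; the region is chosen to contain
artifact and no signal, so minimising it ranks masks by how much streak
energy they remove.

After the search, the five best masks are applied separately and their
outputs averaged voxelwise. Averaging a handful of near-optimal
smoothers suppresses the idiosyncrasies of any single mask's geometry
(each mask has a directional footprint; streaks are radial and hit all
orientations).

## Searching $2^L$ masks

A family of shape $r \times c \times s$ holds $2^{rcs}$ masks
(16, 64, 64, 512 in 2D; 256 up to 134,217,728 in 3D). The all-zero
mask is excluded throughout: it selects no neighbours and its local
mean is undefined.

Small families are enumerated exhaustively. For large ones the package
uses an interval-refinement heuristic (the *optimal response curve*,
ORC):

1. Order all masks along one axis: ascending popcount, then ascending
   integer code within a popcount class. The objective after a masked
   mean is driven primarily by $p$ (see the smoothing law below), so
   this ordering makes the objective quasi-smooth along the axis —
   the property a curve-refinement search implicitly needs. The
   mapping from axis index to mask is computed combinatorially
   (colexicographic unranking), so the $2^{27}$-mask axis is indexed
   lazily and never materialised.
2. Sample 100 evenly spaced axis indices across the current intervals
   (endpoints always included) and evaluate the objective at each.
3. Keep the two sampled indices with the lowest objectives and replace
   the intervals by the spans between each kept index's flanking
   sampled neighbours. Keeping two rather than one hedges against
   multimodality along the axis.
4. Repeat until at most 200 candidates remain (the *pool target*),
   then evaluate the pool exhaustively and rank.

The procedure is seed-free and deterministic; ties are always broken
toward the smaller mask code. On the 3×3×3 family it terminates after
4–5 rounds, i.e. roughly 400–600 objective evaluations out of
1.3×10⁸. Between rounds the package logs the *response curve*
$e^{\gamma E_i} / (e^{\gamma E_i} + e^{\gamma E_{i-1}})$ of successive
round minima ($\gamma = 1$ by default), evaluated in log space. The
refinement loop does not need this quantity to make progress — the
keep-two rule already determines the next intervals — so it serves as
a convergence diagnostic (0.5 means the round improved nothing), with
an optional `early_stop` flag that halts refinement once it settles at
0.5. Treating it as a diagnostic rather than a driver was a deliberate
design choice: no quantitative wiring of the curve into the interval
update is well defined, and the keep-two geometry alone reproduces the
intended budget.

The objective is **pure**: evaluating a mask touches no shared mutable
state, so evaluations may be scheduled concurrently or in any order
with bit-identical results. The package exploits this with an
algebraic shortcut rather than threads: for the masked-mean mode the
per-slice background mean and variance of $B$ are linear and quadratic
forms in the bit vector, so per-slice sums and Gram matrices of the
$L$ shifted background fields are precomputed once and each mask costs
$O(S\,L^2)$ — a matrix-free "parallel" evaluation of hundreds of masks
in milliseconds. The generic apply-then-measure route is kept as an
independent code path and the two are checked against each other in
the test suite.

## Quality metrics

* Background statistics are per-slice population mean/SD over the
  background mask; slices with an empty background are skipped and the
  slice count adjusted.
* SNR pools all ROI voxels: $\mathrm{SNR} = \mu_R / \sigma_R$
  (population $\sigma$). A constant ROI raises a typed error rather
  than returning infinity.
* Contrast ratio is $\mu_R / \mu_B$.
* Percentage change: reduction $(\text{raw} - \text{after})/\text{raw}
  \times 100$, increase $(\text{after} - \text{raw})/\text{raw} \times
  100$; reports round noise/SNR percentages to one decimal and CR
  percentages to two.
* FWHM: profiles are sampled at half-voxel steps with bilinear
  interpolation; the baseline is the median of the outer 20% of
  samples (cold rods sit in a hot plateau, so the plateau level must
  be estimated from the profile ends); half-level crossings are
  located by linear interpolation between bracketing samples. With
  this convention every measurable width on a 700 mm / 168-voxel grid
  is a multiple of 700/168/2 ≈ 2.083 mm.

The background definition deserves a note: "everything outside the
ROI" literally includes the exact-zero corners outside the scan
circle, which would deflate the standard deviation. The package
therefore requires an explicit background mask and provides a helper
that builds the defensible one — outside the object, inside 95% of the
inscribed reconstruction circle, eroded by two voxels.

## The synthetic phantom

No public FBP PET volumes exist for this task, so the package
generates them. The phantom is a Jaszczak-class quality-control
object: a uniform hot cylinder (radius 108 mm) containing six 60°
sectors of cold rods with diameters 31.80, 25.40, 19.10, 15.90, 12.70
and 9.50 mm, rasterised on a 168×168 grid over a 700 mm field of view
(4.167 mm voxels) with identical slices. Rod packing inside a sector
is hexagonal with centre-to-centre pitch equal to twice the rod
diameter — the standard Jaszczak convention — with rods kept clear of
sector borders and the cylinder wall by half a voxel; infeasible
layouts are rejected rather than silently clipped.

Projection is parallel-beam over $[0°, 180°)$ by rotate-and-sum with
bilinear resampling; counting noise is Poisson per bin (slice $z$ uses
seed $\texttt{seed} + z - 1$); reconstruction is FBP with a real-space
Ram-Lak ramp filter (optional Hann window; the unapodised ramp is the
default precisely because it maximises the streaks under study). The
defaults emulate the streak-inducing acquisition: **84 projection
angles**, and a hot-region activity of 4 counts per voxel chosen once
so that the background streak STD is 10–20% of the hot-region mean
(measured: ≈12% on the default grid), a realistic severity for
low-count FBP.

What the simulator deliberately does **not** model: attenuation,
scatter, randoms, detector geometry and ring effects, inter-slice
activity variation, or anatomy. Passing tests on this phantom
therefore demonstrate the operator-search machinery — objective
ranking, budget, reproducibility, the 2D-versus-3D ordering — not
clinical image quality; absolute background STDs from real scanners
are not reproducible from a simulation and are never asserted.

## Numerical choices

* Volumes are processed in 64-bit floating point regardless of on-disk
  dtype.
* Mask anchoring: odd dimensions centre; even dimensions anchor at the
  lower index of the central pair (offset $\lfloor (n-1)/2 \rfloor$).
  Masks are applied flipped, per the convolution convention; symmetric
  masks are unaffected.
* Boundary handling: edge-inclusive mirror padding by default (zero
  padding is available but darkens the rim and corrupts background
  statistics).
* All searches break objective ties toward the smaller mask code, so
  results are reproducible across platforms and evaluation orders.
* Degenerate inputs (all-zero masks, constant ROIs, zero background
  mean, empty-background slices) raise typed errors or warnings rather
  than propagating NaN/Inf.

## Problem sizes used by the test and acceptance runs

The shipped tests and the acceptance script run the full pipeline on a
64×64×8 phantom (the package's desk-scale default for search
experiments; the clinical 168×168 grid is the simulator default for
interactive use). At this size an ORC search of the 3×3×3 family takes
well under a minute, and the multi-seed 2D-versus-3D comparison runs
in seconds per seed. Search behaviour (pool size, evaluation count,
ranking) is grid-independent; only absolute STD values change with
grid and noise level.

## Known limitations

* The axis ordering is a reasoned reconstruction: popcount-major
  ordering makes the objective quasi-smooth, but any ordering of masks
  within a popcount class is somewhat arbitrary, and a pathological
  objective could defeat interval refinement. The exhaustive oracle
  tests bound this risk on enumerable families.
* The masked mean trades resolution for noise exactly as its popcount
  predicts; rods near the voxel scale blur first. FWHM reporting makes
  this visible but the package does not attempt resolution-preserving
  regularisation.
* DICOM series input and `.npy` interchange are not implemented;
  NIfTI-1 and in-memory arrays are the supported routes.
* 2D masks on a single-slice volume and 3D masks on thin volumes rely
  on mirror padding across slices; with very few slices the 3D
  advantage shrinks accordingly.
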