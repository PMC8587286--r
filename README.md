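# streakmso

Streak-artifact reduction in FBP-reconstructed PET volumes by searching
binary morphological structure operators.

## The problem

Filtered back-projection (FBP) is a fast analytic reconstruction method
for PET, but with a limited number of projection angles and Poisson
counting noise it produces radial *streak artifacts* in the image
background. `streakmso` suppresses these streaks with small binary masks
("morphological structure operators", MSOs): a mask `A` of shape
`r x c` (2D, applied slice by slice) or `r x c x s` (3D, smoothing
across slices) with entries `a_i ∈ {0, 1}`, where 1 marks a neighbour
whose signal is kept and 0 a position excluded from the local operation.
Applied as a **masked local mean** (the default; a normalized
convolution with the flipped 0/1 kernel),

    B(x) = (1/p) Σ_{k : A(k)=1} X(x − k + a),    p = popcount(A),

each mask defines one candidate denoiser; a grayscale **opening**
(erosion then dilation with `A` as flat structuring element) is provided
as the classical alternative reading.

A family of shape `r x c (x s)` contains `2^(r·c·s)` masks — 512 for
3×3, but 134,217,728 for 3×3×3 — so the package searches the family for
the masks that minimise the mean per-slice population standard deviation
of a designated streak-bearing background region:

* **exhaustive search** for small families, and
* an **optimal-response-curve (ORC) interval refinement** for large
  ones: order all masks along one axis (ascending popcount, then code),
  evaluate 100 evenly spaced candidates, keep the two best, zoom into
  the spans around them, and repeat until at most 200 candidates remain;
  those are evaluated exhaustively. A few hundred objective evaluations
  replace 1.3×10⁸.

The five best masks are averaged into the final denoised volume, and
quality is quantified by background STD, ROI signal-to-noise ratio
(SNR = μ/σ), contrast ratio (CR = ROI mean / background mean),
percentage changes against the raw volume, and FWHM measured on line
profiles across the phantom's cold rods.

Because no public scan data exist for this task, the package includes a
digital Jaszczak-style phantom simulator (uniform hot cylinder, six
60° sectors of cold rods with diameters 31.80–9.50 mm, 168×168 grid
over a 700 mm FOV) with parallel-beam forward projection, Poisson
noise, and ramp-filtered back-projection, so every result is
reproducible from a seed.

## Worked example

Simulate a streaky phantom, search the full 3×3×3 family, denoise, and
evaluate:

```r
library(streakmso)

spec <- phantom_spec(grid_size = 64, n_slices = 8, seed = 7)
sim  <- simulate_fbp_phantom(spec, n_angles = 84)

res <- orc_search(sim$recon, c(3, 3, 3), sim$masks$background)
res
#> <search_result> 3x3x3 family, orc, 424 objective evaluations
#>       code  objective popcount
#>  134217727 0.06146600       27
#>  134209535 0.06223200       26
#>  134213631 0.06223276       26
#>  134152191 0.06224321       26
#>  134217215 0.06224385       26

den <- apply_mask_set_average(sim$recon, res$top_masks)
raw_sd <- mean_background_std(sim$recon, sim$masks$background)
den_sd <- mean_background_std(den, sim$masks$background)
pct_change(raw_sd, den_sd, "reduction")
#> raw 0.2950 -> denoised 0.0614: reduction 79.2%
```

The search touched 424 of the 134,217,727 candidate masks and its
top-5 ranking is dominated by high-popcount masks, as expected: the
masked mean of `p` voxels shrinks i.i.d. background noise by `1/√p`.
Averaging the top five masks cuts the mean background STD from 0.295
to 0.061 (a 79.2% reduction) while the hot-region SNR rises from 6.6
to 31.3. On clinical-resolution data the same flow runs per volume via
the YAML-configured pipeline:

```r
rec <- run_denoise_pipeline(list(
  simulate = list(grid_size = 64, n_slices = 8, n_angles = 84),
  shape = "3x3x3", seed = 7,
  output = list(volume = "denoised.nii.gz", record = "run.json")))
```

or from a shell through `inst/cli/streakmso.R`
(`simulate | search | denoise | evaluate | compare`).

## Conventions

Volumes are `values[row, col, slice]` arrays in 64-bit floating point
with physical mm coordinates at voxel centres; NIfTI-1
(`.nii`/`.nii.gz`) is the on-disk format, with voxel spacing in the
header. Masks serialise as JSON `{"shape": [r, c, s], "code": n}`.
Odd mask dimensions anchor at their centre, even ones at the lower
index of the central pair; borders use edge-inclusive mirror padding by
default.
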