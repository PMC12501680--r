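# dimqa — diffusion instability measure for HARDI phantom QA

Quality assurance for diffusion-MRI scanners, aimed at physicists and QA
operators who run regular phantom scans. A sphere filled with silicone oil
has practically no diffusion (apparent diffusivity ~10⁻⁶ mm²/s), so every
diffusion-weighted volume of a HARDI acquisition should be a near-identical
copy of the b₀ image at any b-value up to 10 000 s/mm² and beyond. Treating
the series as a "time series" of a stationary object, any decorrelation
between volumes is scanner instability — changing EPI ghosts, RF drift,
parallel-imaging reconstruction errors — not physiology.

## The statistic

With `X ∈ ℝ^(Nv×Nd)` the masked phantom voxels of the `Nd`
diffusion-weighted volumes, each column centered and normalized to `X̂`,
the matrix `C = X̂ᵀX̂` holds the Pearson correlations between
diffusion-encoding directions. The **diffusion instability measure** is

```
DIM = 1 − max λᵢ / Σ λᵢ ,     λᵢ = eigenvalues of C,
```

reported in parts per million. Identical volumes give a rank-one `C` and
DIM = 0; mutually uncorrelated volumes push DIM toward its ceiling
`1 − 1/Nd`. Around the statistic the package provides the full pipeline:
NIfTI + FSL bval/bvec input, automatic phantom masking, slice-wise
translation-only registration to the first EPI volume, direction-subset
policies (exclude a suspect volume), voxel-subsampling stability curves,
a log-ratio diffusivity check of the phantom filling, and a synthetic
spherical-phantom generator with parameterized noise, EPI half-FOV
ghosting, intensity/positional drift and single-volume corruption.

## Worked example

```r
library(dimqa)

# a clean scan and one whose first direction carries a heavy (50%) ghost
clean <- generatePhantom(simulationConfig(snr = 100, seed = 1))
bad   <- generatePhantom(simulationConfig(snr = 100, corruptDirections = 1,
                                          corruptAmplitude = 0.5, seed = 1))

mask <- makePhantomMask(bad)
mask
#> PhantomMask: 73210 voxels on a 96 x 96 x 48 grid (N_v = 73210)

dimFromDataset(bad, mask = mask, subsetPolicy = "all")
#> DimResult: DIM = 27907.31 ppm (raw 2.791e-02)
#>   N_v = 73210, N_d = 64, policy = all, registered = FALSE
#>   lambda_max = 62.2139, lambda_min = 1.936e-02

dimFromDataset(bad, mask = mask, subsetPolicy = "exclude_first")
#> DimResult: DIM = 20331.87 ppm (raw 2.033e-02)
#>   N_v = 73210, N_d = 63, policy = exclude_first, registered = FALSE
#>   lambda_max = 61.7191, lambda_min = 1.936e-02

dimFromDataset(clean, mask = mask)
#> DimResult: DIM = 20336.67 ppm (raw 2.034e-02)
#>   N_v = 73210, N_d = 64, policy = all, registered = FALSE
#>   lambda_max = 62.6985, lambda_min = 1.936e-02

estimateDiffusivity(clean, mask)
#> DiffusivityEstimate: mean D = 1.050e-06 mm^2/s over 64 directions (b = 1000)
```

Read: the single ghost-corrupted volume inflates DIM from ~20 300 to
~27 900 ppm; dropping that one direction (`exclude_first`) brings it back
to the clean-scan level, which is how a bad volume is diagnosed in
practice. The diffusivity check confirms the near-zero-diffusion premise
(true simulated value 10⁻⁶ mm²/s). The methods vignette
(`vignettes/dim-methods.Rmd`) documents the model, the simulator, and
every numerical design choice.

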