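Package: dimqa
Title: Diffusion Instability Measure for HARDI Phantom Quality Assurance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality assurance for diffusion MRI scanners from HARDI
    acquisitions of a uniform silicone-oil phantom. Computes the diffusion
    instability measure (DIM), one minus the eigenratio of the
    inter-direction Pearson correlation matrix, reported in parts per
    million, together with the surrounding pipeline: NIfTI/bval/bvec
    input, automatic phantom masking, slice-wise translation-only
    registration, voxel-subsampling stability curves, a log-ratio
    diffusivity check of the phantom filling, and a synthetic
    spherical-phantom generator with parameterized noise, EPI half-FOV
    ghosting, intensity drift, positional drift, and single-volume
    corruption for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'diffusivity.R'
    'dim-core.R'
    'hardi-io.R'
    'registration.R'
    'report.R'
    'simulate.R'
    'stability.R'
    'utils.R'
RoxygenNote: 7.3.3
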