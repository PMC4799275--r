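Package: dicopp
Title: Lossless Temporal-Delta Compression for Dynamic CT Perfusion Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lossless compression of dynamic (4D) CT perfusion image series by
    temporal delta encoding: each voxel's time series is stored as its temporal
    minimum plus variable-width packed differences, giving constant-time random
    read access to any single intensity directly from the compressed arrays.
    Includes compressed-domain double-threshold masking that prunes voxels from
    their per-voxel intensity bounds without touching packed bits, a bit-exact
    on-disk container format with checksums, readers for DICOM series, NIfTI and
    raw headered volumes, a synthetic CT-perfusion phantom generator (gamma-variate
    contrast kinetics, noise, optional motion) so no patient data are required,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
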