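Package: bundleatlas
Title: Probabilistic Multi-Scale White-Matter Bundle Atlases from Tractography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect whole-brain tractograms into region-pair
    white-matter bundles, aggregate them across subjects into spatial
    probabilistic anatomical maps (SPAMs) and group connectivity matrices
    with distance-dependent consensus thresholding, serialize the result in
    a compact HDF5 atlas layout, and apply an atlas to arbitrary scalar
    volumes to obtain connection-weighted matrices, ROI bundle queries and
    lesion "dysconnectome" reports. Includes streamline geometry utilities
    (length, winding, resampling, minimum direct-flip distance, compression,
    point-wise spatial transforms), test-retest agreement statistics
    (Bland-Altman, Lin's concordance, Pearson with FDR control) and a seeded
    synthetic phantom generator so the whole pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
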