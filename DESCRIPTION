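Package: ccmprofiles
Title: Causal Interaction Profiles for Eigenmode Timeseries via Convergent
    Cross Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds lag-scanned convergent cross mapping (CCM) interaction
    profiles between behavioral eigenmode timeseries (e.g. the four leading
    'eigenworm' postural modes of Caenorhabditis elegans). Provides the
    simplex-projection cross-mapping engine with time-delay embedding,
    library resampling and a Theiler exclusion window; per-pair delay-versus-
    skill interaction profiles with min-max normalization and strain
    averaging; Fourier phase-randomized surrogate nulls; Spearman profile
    similarity and a directional permutation test for group distinctness;
    an optimal embedding dimension scan; coupled logistic map and synthetic
    eigenmode simulators for validation; and CSV readers, filters and a
    command-line interface for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
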