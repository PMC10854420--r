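Package: plasmacnv
Title: Copy-Number Profiling and ctDNA Quantification from Shallow WGS of
    Plasma Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circulating tumor DNA (ctDNA) detection in
    uveal melanoma from shallow whole-genome sequencing of plasma cell-free
    DNA. Implements in silico fragment-size selection (80-150 bp), megabase
    binning of aligned fragments with mapping-quality filtering, GC correction
    and normalization against least-affected reference chromosomes (2q, 4,
    12q), a hidden-Markov-model copy-number caller with grid-search tumor
    fraction estimation, a fixed-threshold segment caller, in silico spike-in
    dilution experiments that measure the limit of detection for chromosome 3
    loss and chromosome 8q gain, and Poisson-corrected droplet digital PCR
    quantification of ctDNA in copies per millilitre of plasma. A synthetic
    plasma cfDNA simulator (admixed tumor copy-number profiles, GC bias,
    fragment-length mixtures, overdispersed counts) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    yaml
Config/testthat/edition: 3
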