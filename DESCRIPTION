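Package: sfcurate
Title: Biocuration Toolkit for Functionally Diverse Enzyme Superfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating functionally diverse enzyme superfamilies
    along a superfamily/subgroup/family hierarchy. Reduces large homologous
    sequence sets to bounded, diversity-sampling seed sets; builds
    position-specific scoring profiles from seed alignments; calibrates
    trusted, noise and gathering bit-score thresholds from ranked hit
    tables; transfers annotations down the hierarchy gated by conserved
    catalytic residue checks; and builds, thresholds and exports sequence
    similarity networks (XGMML) for curation. Includes a synthetic
    superfamily generator with planted conserved residues and known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'sfcurate-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'esfo.R'
    'backend.R'
    'calibrate.R'
    'annotate.R'
    'io.R'
    'seed.R'
    'show-methods.R'
    'ssn.R'
    'synth.R'
    'xgmml.R'
    'zip.R'
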