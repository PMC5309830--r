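Package: indelScope
Title: Quantification of CRISPR-Cas9 Editing Outcomes from Targeted
    Amplicon Deep Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@indelscope.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of targeted-amplicon deep-sequencing
    experiments that assay CRISPR-Cas9 editing outcomes in a cell
    population: adapter and quality trimming of paired 2x300 reads,
    exhaustive-offset merging of overlapping mates, affine-gap semi-global
    alignment of merged reads to the reference amplicon with left-normalized
    indel calling, per-read classification of coding consequence
    (frameshift, in-frame, noncoding), splice-window disruption, premature
    stop codons and residue-level protein changes, a disruptive-mutation
    call with field-standard thresholds, and per-sample summaries with
    cross-passage stability testing (Wilson intervals and two-proportion
    tests). A seeded read simulator with a per-read truth manifest provides
    ground-truth data for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: CRISPR, Sequencing, Alignment, SequenceMatching, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'indelScope-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'align.R'
    'amplicon-io.R'
    'events.R'
    'classify.R'
    'guide.R'
    'simulate.R'
    'summarize.R'
    'pipeline.R'
    'read-prep.R'
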