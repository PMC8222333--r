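Package: SpecProfiler
Title: Specificity Profiling and Editing Quantification for Engineered CRISPR-Cas12a Nucleases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize CRISPR-Cas12a nucleases from sorted-library
    sequencing experiments. Implements design of mismatch and PAM variant
    libraries, tallying of sequencing fractions into variant count tables,
    log-ratio estimators of relative binding affinity (Spec-seq) and cleavage
    depletion (SEAM-seq), additive per-position mismatch-penalty (energy
    matrix) models with motif-logo output, PAM preference profiling, NGS-based
    enrichment analysis of directed-evolution selections, amplicon-based
    indel/HDR editing quantification with cut-site window rules, and
    dose-response (EC50) and cleavage-kinetics curve fitting. A synthetic-data
    module generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CRISPR, Sequencing, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SpecProfiler-package.R'
    'ampliconEditing.R'
    'targetSite.R'
    'libraryDesign.R'
    'fractionCounts.R'
    'specificity.R'
    'pamProfiling.R'
    'responseFits.R'
    'selection.R'
    'plots.R'
    'simulate.R'
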