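Package: clpbmimic
Title: Gut Bacterial ClpB-Like Gene Function, Alpha-MSH Molecular Mimicry
    and Host Phenotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit linking a gut-bacterial ClpB-like gene
    function (KEGG ortholog K03695) to host phenotype. Implements
    KEGG-function read-count profiling from annotated metagenomic ORFs
    (best annotation per ORF, read-to-ORF assignment, contingency tables,
    relative abundance, low-abundance taxon filtering), a molecular-mimicry
    screen for the alpha-MSH hexapeptide epitope (RWGKPV) over predicted
    protein sequences with semi-global BLOSUM62 alignment, epitope-window
    trimming and family-level identity summaries, orthogonal projection to
    latent structures (O-PLS) regression of metabolite matrices with
    seven-fold cross-validated Q2Y and permutation validation, probabilistic
    quotient normalization, and cohort-level statistics (test dispatch,
    Spearman and partial Spearman correlation, multiple linear regression,
    Benjamini-Hochberg adjustment). A synthetic-data module generates all
    inputs with planted ground truth so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    car,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
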