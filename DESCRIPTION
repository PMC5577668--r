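Package: neoscape
Title: Neoepitope Discovery from Somatic Missense Mutations and Gene Fusions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies candidate MHC class I neoepitopes in tumor genomes from
    two classes of somatic alteration: missense single-nucleotide variants and
    expressed gene fusions. Tiling nonamer peptide windows are generated around
    each amino-acid substitution and across each in-frame fusion junction,
    scored for predicted HLA binding affinity through a pluggable predictor
    interface (an output-file adapter for external predictors plus a
    deterministic built-in position-weight scorer), and filtered at the
    conventional 500 nM IC50 cutoff. RNA-seq alignments attach expression
    evidence to each candidate via mutant-allele read support with a full
    27-base window-span requirement. Additional components score concordance of
    sequencing-derived HLA class I genotypes against clinical typing, summarize
    cohort allele carrier frequencies, and aggregate per-sample and cohort
    neoepitope landscape reports. A deterministic synthetic-fixture generator
    with planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImmunoOncology, SomaticMutation, Transcriptomics, Sequencing
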