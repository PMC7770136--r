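Package: conskit
Title: Conservation Genomics of Inbreeding and Genetic Load from
    Multi-Sample VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing genetic diversity, inbreeding and
    mutational load in small populations from multi-sample VCFs of
    diploid genomes. Implements GATK-style hard filtering of biallelic
    autosomal SNVs, KING-robust pairwise kinship from identity-by-state
    counts with greedy pruning of consanguineous individuals, windowed
    heterozygosity and pairwise nucleotide mismatch in 100-kb tiles,
    sliding-window detection of runs of homozygosity (ROH) with the
    genomic inbreeding coefficient F_ROH and length-based generation
    dating, and ancestral-allele polarization against outgroups to count
    per-individual homozygous-derived loss-of-function, missense and
    synonymous variants. A synthetic diploid cohort generator plants
    heterozygosity, autozygous tracts, pedigree relationships and
    functional-effect classes with machine-readable ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, VariantAnnotation, SNP, Sequencing, PopulationGenetics
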