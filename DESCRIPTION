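Package: twinsnv
Title: Monozygotic Twin Discrimination from Replicated SNV Genotypes
Version: 0.1.0
Authors@R: person("Forensic", "Genomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for distinguishing monozygotic twins from shotgun and
    targeted sequencing genotypes. Implements per-replicate genotype
    acceptance with depth, quality, heterozygote-balance and homozygote-noise
    filters, within-sample replicate-concordance consensus, cross-sample
    discordance detection with a heterozygote-balance stringency sweep,
    targeted-panel confirmation of candidate loci, and a twin-pair read-count
    simulator (germline, post-zygotic and tissue-specific somatic variants)
    that emits VCFs plus ground truth so the whole pipeline can be exercised
    without access to case data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
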