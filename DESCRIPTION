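Package: hetpair
Title: Clonal Relatedness of Paired Tumour Components from Somatic
    Variants, Mutational Signatures, Copy Number and Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether two macrodissected components of a single
    tumour (for example the E-cadherin negative and aberrant regions of an
    invasive lobular breast carcinoma) are clonally related or arose as a
    collision of independent lesions. Builds multi-caller consensus somatic
    callsets from per-caller VCFs, applies a fixed post hoc filter chain
    with a per-variant audit trail, computes shared/private partitions and
    overlap coefficients, six-class substitution spectra and 96-channel
    trinucleotide mutational-signature profiles with cosine similarity to a
    reference catalogue, ploidy-adjusted per-gene copy-number states with
    LOH calls, differential promoter-methylation detection on beta values,
    and a binomial-mixture subclone detector. Ships a paired-tumour
    simulator with known ground truth (truncal fraction, signature mixture,
    subclones, caller error profiles, planted copy-number and methylation
    events) so the whole pipeline is testable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
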