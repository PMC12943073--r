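Package: rrnalloc
Title: Scaling of Bacterial Translation Machinery with Growth Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomic analysis of the bacterial translation
    machinery. Parses GenBank flat files to inventory rRNA (rrn) operons
    and tRNA genes per amino acid, computes genome-wide codon and
    amino-acid usage (including relative synonymous codon usage and codon
    family sizes), fits exponential-decay-with-floor models relating rrn
    operon and tRNA gene counts to generation time by profile maximum
    likelihood with likelihood-ratio tests, and fits an ordinary
    least-squares model predicting per-amino-acid tRNA gene counts from
    amino-acid usage and codon family size, with full ANOVA. Includes
    generators for annotated synthetic genomes and simulated datasets so
    the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
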