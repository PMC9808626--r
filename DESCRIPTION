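Package: methylsnp
Title: Hairpin Bisulfite Read Deconvolution, Methylation Quantification
    and Reference-Free Methyltransferase Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for hairpin-linked bisulfite sequencing, in which each
    DNA fragment is sequenced together with an unconverted copy of itself.
    Per-cycle comparison of the converted read (Read1) and the four-base
    copy read (Read2) recovers the original genomic sequence and the
    methylation state of every covered cytosine. The package provides a
    protocol-faithful read-pair simulator with ground truth, adapter
    trimming and pair deconvolution (reference-free, plus empirical
    Bayesian base-quality calibration against a reference), post-alignment
    filters (unique mapping by AS/XS, position-and-sequence duplicate
    marking, XM methylation tags, non-conversion filtering), per-site and
    per-region methylation quantification with conversion-rate estimation
    and allele-specific read splitting, and reference-free discovery of
    methyltransferase recognition motifs by binomial 8-mer enrichment,
    hierarchical clustering and IUPAC consensus calling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
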