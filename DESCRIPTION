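Package: eigenstratr
Title: Chunked Processing of EIGENSTRAT and Packed ANCESTRYMAP Genotype Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reads, filters, transforms, summarizes and converts genotype
    datasets stored as EIGENSTRAT triples (.geno/.snp/.ind), in either the
    text encoding or the packed-binary ANCESTRYMAP encoding, using
    memory-bounded chunked streaming so that datasets larger than memory can
    be processed. Supports population and individual subsetting, SNP
    selection by identifier, genomic region or chromosome, minor allele
    frequency and missingness filtering with sex-chromosome-aware
    denominators, random pseudo-haploidization, ancestral-allele
    polarization, genetic-map re-interpolation, in-place metadata updates
    with automatic backups, and bidirectional text/binary conversion. A
    command-line entry point drives the full pipeline; the underlying
    readers, statistics and filters are exported for use in custom analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
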