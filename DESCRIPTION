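Package: venomtx
Title: Curation and Molecular Evolution Analysis of Multiplexed Venom-Gland Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating venom-gland transcriptome assemblies from
    multiplexed sequencing runs and analysing the molecular evolution of the
    recovered toxins. Implements k-mer based cross-sample contamination read
    filtering, complete open-reading-frame discovery and toxin family
    annotation by local protein alignment, read mapping with coverage-based
    chimeric-contig screening, three-indicator species-of-origin assignment,
    greedy isoform clustering at a configurable identity threshold,
    transcripts-per-million expression profiling, and Nei-Gojobori (1986)
    dN/dS selection analysis with the accompanying tree utilities (Newick
    input/output, midpoint rooting, clade extraction). A synthetic-data
    module generates multiplexed venom-gland-like libraries, contigs,
    planted chimeras and codon alignments evolved under a known dN/dS ratio
    so that every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
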