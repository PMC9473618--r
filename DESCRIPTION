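Package: repeatcnr
Title: Repeat-Centric Analysis of nanoCUT&RUN Chromatin Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies chromatin-profiling signal (CUT&RUN and related
    tethered-nuclease assays) on repetitive DNA, where peak calling on
    uniquely mapped reads breaks down. Provides per-repeat-family read
    counting with RPM normalization, IP over control enrichment with a dual
    top-quantile filter, read pileup profiles along repeat consensus
    sequences via consensus-dimer mapping and monomer folding, canonical
    tandem simple-repeat (k-mer) detection and enrichment calling, and
    binned coverage tracks split by mapping uniqueness. Includes a seeded
    synthetic-data generator that emulates telomeric retrotransposon arrays,
    centromeric repeat islands and satellite tracts for end-to-end testing,
    plus a minimal deterministic read assigner and plain-SAM ingestion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
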