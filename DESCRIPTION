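Package: crispecc
Title: Quantification of Multiplexed CRISPR Editing Outcomes and Small
    eccDNA Circularization Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying multiplexed CRISPR/Cas9 editing outcomes
    from targeted amplicon deep sequencing and for characterizing small
    extrachromosomal circular DNA (eccDNA). Reads are aligned to their target
    amplicons, editing outcomes are classified relative to the Cas9 cleavage
    position using the cut-anchored "Del a|b" / "Ins n seq" allele notation,
    and per-target allele tables with a configurable true-mutation frequency
    threshold are produced. Allele-frequency profiles can be compared across
    clonal lineages (parental clones, subclones, time courses, grafts) to
    detect gain and loss of alleles. A split-read circularization-junction
    caller detects eccDNA on small references, canonicalizes junctions under
    microhomology, annotates circles against genic features, and relates
    junction coordinates to Cas9 cut sites. A synthetic-data generator
    produces amplicon read sets, clonal lineages, and rolling-circle
    amplified eccDNA libraries with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
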