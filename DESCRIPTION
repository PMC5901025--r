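Package: endorecruit
Title: Fragment Recruitment Analysis for Endophyte Detection in Holobiont
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether a candidate bacterial genome is genuinely
    resident in a host-plus-microbiome ("holobiont") shotgun metagenome.
    Read-to-genome alignments are scored by percent identity, binned in
    position-by-identity space to build fragment recruitment plots, and
    summarized into presence/absence verdicts that distinguish true endophytes
    from recruitment artifacts caused by universally conserved loci (such as
    rRNA operons) and chimeric assembly scaffolds. Companion modules summarize
    rRNA-based taxonomic profiles (host-taxon masking, relative abundance,
    Shannon diversity, rarefaction, habitat overlap), screen host genome
    assemblies for bacterial scaffolds, and simulate holobiont communities
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
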