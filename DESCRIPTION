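Package: wrkykit
Title: Rule-Based Annotation and Expression Analysis of Grapevine WRKY
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the WRKY transcription-factor family in
    grapevine (Vitis spp.): detection of WRKY domains by the conserved
    WRKYGQK heptapeptide plus a zinc-finger spacing grammar, group and
    subgroup classification, scanning for accessory motifs (LXXLL,
    LXLXLX/EAR-like, HARF, leucine-zipper heptads, W-box), protein
    molecular-weight and isoelectric-point computation, neighbor-joining
    phylogenies of WRKY domains with bootstrap support, and qRT-PCR
    delta-delta-Ct response calling. Ships a machine-readable catalog of
    the published grapevine WRKY family and synthetic-data generators for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
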