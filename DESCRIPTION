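Package: mosaicedit
Title: Quantify Mosaic CRISPR/Cas9 Editing from Sanger Base-Call Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CRISPR/Cas9 editing of paralogous genes from Sanger
    sequencing of mixed-template PCR amplicons. Implements a per-position
    sequence fidelity score comparing primary/secondary base calls of an
    edited sample against an aligned wildtype control read (with IUPAC
    ambiguity handling and a 10-base moving average), indel calling and
    frame-consequence classification for cloned amplicon sequences,
    allele-selective sgRNA protospacer/PAM matching with predicted cut
    sites and re-cleavage checks for HDR templates, and a synthetic
    mosaic-editing simulator (NHEJ-like indel spectra, mixed-template
    trace rendering, clone sampling) that closes the loop for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
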