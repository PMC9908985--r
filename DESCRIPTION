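Package: domassign
Title: Quality Control, Chopping and Superfamily Assignment of Predicted Protein Domain Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for classifying predicted protein structure models (AlphaFold-style,
    with per-residue pLDDT in the B-factor column) into structural superfamilies.
    Implements confidence and globularity quality filters (mean pLDDT, long unordered
    regions, secondary-structure order fraction, hydrophobic packing density, grid-based
    solvent-excluded surface area/volume), optimal resolution of overlapping domain hits,
    chopping of domains out of overlapping model fragments, a threshold cascade of
    structure-comparison scans against a labelled domain library, and single-linkage
    clustering of unassigned domains into putative new superfamilies with multidomain
    triage. Ships a deterministic synthetic-structure generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    digest,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
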