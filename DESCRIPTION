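Package: coralfp
Title: Gene-Family Expansion Analysis for Coral Fluorescent Proteins
Version: 0.1.0
Authors@R: person("Marine Genomics", "Tools", email = "devnull@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying the expansion of the
    GFP-like fluorescent protein (FP) gene family in acroporid corals:
    candidate gene identification by local-alignment search and
    position-specific domain scan, multi-domain model splitting and
    completeness filtering, chromophore-tripeptide extraction,
    neighbor-joining phylogeny with bootstrap support and clade-based
    color classification (GFP/CFP, RFP, chromoprotein), duplication-loss
    parsimony reconciliation against a species tree with per-branch event
    ledgers and ancestral copy numbers, tandem-cluster and gene-order
    synteny analysis, and a birth-death simulator of FP family evolution
    that emits FASTA/GFF3/Newick plus a ground-truth event log so every
    stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
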