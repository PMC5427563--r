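Package: ppidock
Title: Protein Dimer Model Evaluation and Structure-Based Interaction Network Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke stages of an across-proteome protein dimer
    modeling and protein-protein interaction (PPI) network pipeline: interface
    and contact-map extraction, interface RMSD (iRMSD) and pairwise contact
    score (PCS) model-quality metrics, docking success rates and the
    sampling/scoring failure spectrum, ligand-swap negative-set construction,
    a random-forest interaction classifier on binding-energy features with
    MCC-optimal threshold selection and top-n aggregation, Gene Ontology slim
    co-annotation filters, and PPI network assembly with topology comparison
    against random graph nulls. Includes a synthetic-data generator producing
    toy rigid dimers, controlled decoy sets, class-conditional energy features
    and annotation maps, so the full pipeline is testable end-to-end without
    external docking engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    ranger,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
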