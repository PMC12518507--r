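Package: pepdockeval
Title: Evaluation and Interpretability Metrics for Protein-Peptide Docking Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score predicted protein-peptide complex structures against
    experimental references and to probe the sequence inputs such predictions
    depend on. Implements DockQ (Fnat, interface RMSD, ligand RMSD) with CAPRI-style
    quality categories, an atomic-accuracy criterion, TM-score, peptide RMSD after
    receptor alignment, and a distogram-based contact-map statistic (RMSD_map) for
    sequence-masked predictions. Provides paired multiple sequence alignment
    construction with species matching, a pairing-shuffle null model, inter-chain
    mutual information, Jensen-Shannon conservation profiling, hydrophobicity
    summaries, and a dated-library binding-site-match search that quantifies
    training-set overlap. Seeded generators produce synthetic two-chain complexes,
    controlled-error predictions, coevolving alignments, and planted match
    libraries so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
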