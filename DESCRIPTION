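Package: tcrphosdyn
Title: Rule-Based Modeling and Phosphoproteomic Analysis of Early T-Cell
    Receptor Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the first minute of T-cell receptor (TCR) and
    CD28 co-stimulation at phosphosite resolution.  Provides a reader, writer
    and validator for a subset of the BioNetGen language (BNGL) describing
    rule-based kinetic models; a network-free particle-based stochastic
    simulator (Gillespie direct method over rule embeddings) with
    equilibration, in-silico knockdowns and run averaging; a reconstructed
    rule-based model of proximal TCR/CD28 signaling covering LCK, ZAP70, LAT,
    LCP2, PLCG1, WAS, PTPN6, PAG1, DOK1 and DOK2 phosphosites, including
    PTPN6-mediated positive feedback and an NCK-CD3E shortcut route to WAS;
    a SILAC phosphoproteomic time-course pipeline (proline-conversion
    correction, least-modified-peptide site collapse, replicate averaging,
    fold-change regulation filtering, fuzzy c-means clustering, PCA-based
    site classification, and Fisher/Benjamini-Hochberg term enrichment);
    parameter estimation by coarse grid search with quasi-Newton refinement
    under common random numbers; and synthetic-data generators with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
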