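Package: genere
Title: Semi-Supervised Multi-View Ensemble Reconstruction of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the edge scores produced by many gene regulatory network
    inference methods into a single calibrated probability per candidate
    regulatory interaction, learning from only-positive (and possibly empty)
    sets of known interactions. Base-method scores are partitioned into weakly
    correlated views by clustering feature columns (PCA loadings or K-means);
    each view trains a bagged ensemble of "non-traditional" classifiers on
    positive and sampled unlabeled interactions, corrected to a positive-class
    posterior via the Elkan-Noto label-frequency estimate; views exchange
    their most confident predictions across iterations (co-training with
    retraction). Includes Borda and top-k rank-combination baselines,
    threshold-free AUROC/AUPRC evaluation against a gold standard, readers
    and writers for DREAM-style ranked edge lists, and a synthetic-data
    generator producing ground-truth networks and correlated groups of
    base-method score matrices for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
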