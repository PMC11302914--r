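Package: msaDenoise
Title: Confidence-Guided Denoising of MSA Cluster Profiles by Gradient Descent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns an additive bias ("residual") to the cluster profile of a
    multiple sequence alignment by gradient descent through a differentiable
    fold-confidence backend, minimizing the inverse of the ranking confidence
    (0.8*iptm + 0.2*ptm). Provides A3M/FASTA alignment I/O with deletion
    counts and species labels, AlphaFold-style featurization (cluster
    sampling, profile computation, species pairing and block diagonalization
    for multimers, profile corruption), an Adam optimizer over the profile
    bias, a planted-ground-truth synthetic surrogate backend so the whole
    optimization and selection loop is testable at desk scale, and the
    confidence/accuracy evaluation statistics (success and hidden-failure
    classification, Spearman correlation, ROC-AUC of confidence as a model
    selector, running-mean curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
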