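Package: ecgsubband
Title: Sub-Band Hjorth and Entropy Features for ECG Rhythm Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification of short single-lead ECG
    segments into atrial fibrillation (AF), congestive heart failure (CHF)
    and normal sinus rhythm (NSR). Segments are amplitude-normalized,
    decomposed by a five-level discrete wavelet transform into six
    sub-bands, and each sub-band is summarized by the three Hjorth
    descriptors (activity, mobility, complexity) and six entropy measures
    (Shannon wavelet-energy, sample, permutation, dispersion, bubble and
    slope entropy), yielding a 54-dimensional feature vector. Includes a
    one-way ANOVA feature screen, grid-search hyperparameter tuning with
    stratified five-fold cross-validation for k-NN, SVM, random forest,
    feed-forward neural network and radial basis function network
    classifiers, a seeded synthetic three-class ECG generator for
    download-free experiments, and an end-to-end pipeline with a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    randomForest,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
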