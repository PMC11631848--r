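Package: esibench
Title: Simulation and Benchmarking of Linear and Learned EEG Source Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained benchmark for spatio-temporal EEG source imaging
    (ESI). Builds an analytic three-shell spherical head model with a synthetic
    cortical parcellation and regional leadfield, simulates paired
    (source, EEG) data with two independent generators (event-related Gaussian
    waveforms on graph-grown extended regions, and Jansen-Rit neural-mass
    dynamics with interictal-spike extraction), solves the inverse problem with
    regularized minimum-norm estimation (MNE) and sLORETA as well as three
    trainable inverse operators (a wide 1D-CNN, a bidirectional LSTM and a
    deepSIF-style spatio-temporal network, trained with a cosine-similarity
    loss and global-field-power rescaling), and evaluates all methods with a
    five-metric suite (localization error, extent AUC, nMSE, PSNR, peak-time
    error) plus ANOVA/Tukey method comparison, both in-domain and across
    simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
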