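Package: stncoupling
Title: Cortico-Subthalamic Oscillatory Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of oscillatory communication between cortex and the
    subthalamic nucleus from multisite intracranial recordings
    (electrocorticography and deep-brain-stimulation lead local field
    potentials). Implements preprocessing (notch/bandpass filtering,
    epoching, artifact-epoch rejection, period-based stimulation-artifact
    removal, bipolar referencing, bootstrap segmentation), multitaper power
    spectra with percent-total normalisation and spatio-spectral
    decomposition, undirected and directed multivariate spectral coupling
    (imaginary coherency, maximised imaginary coherency with spatial
    patterns, time-reversed spectral Granger causality), bispectral
    time-delay estimation with bootstrap confidence screening and local-peak
    binning, non-parametric paired permutation tests with cluster
    correction, and linkage of coupling spatial patterns to structural
    (streamline-count) and functional (seed-map) connectivity via linear
    mixed-effects models. A synthetic-data module generates recordings,
    connectome fixtures and cohort tables with known ground truth for
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    lme4,
    lmerTest,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
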