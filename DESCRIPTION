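Package: v1gamma
Title: Thalamocortical Model and Spectral Information Analysis of Narrow- and
    Broad-Band Gamma in Mouse V1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a sparse recurrent excitatory-inhibitory network of
    conductance-based leaky integrate-and-fire neurons driven by a
    two-component thalamic input (a sustained rate and a ~57 Hz band-limited
    periodic rate, plus 1/f^1.5 colored noise), and computes a local field
    potential (LFP) proxy from the absolute synaptic currents onto excitatory
    neurons.  Provides the accompanying analysis chain for contrast-dependent
    gamma-band dynamics in mouse primary visual cortex: Welch power spectra
    and spectral modulation relative to a reference contrast, generalized
    Morse-wavelet scalograms segmented around grating contrast reversals,
    threshold-based derivation of the narrow ([45-65] Hz) and broad
    ([20-45] and [65-95] Hz) gamma bands, band modulation time courses and
    onset latencies, bias-corrected mutual information between contrast and
    band modulations with synergy and minimum-information redundancy
    decomposition, reduced chi-square grid-search fitting of the thalamic
    input parameters, Hilbert-phase entrainment measures, and a parametric
    surrogate-LFP generator for end-to-end validation of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
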