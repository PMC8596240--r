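Package: axonmea
Title: Evoked Axonal Activity Analysis for Microfluidic Multi-Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of extracellular recordings from neuronal
    axons isolated in the microchannels of a PDMS microfluidic chip aligned
    with a 60-electrode array. Provides a forward model of such recordings
    (spontaneous bursts, stimulus-evoked direct and synaptic responses
    propagating along microchannels, optical stimulation artifacts,
    pharmacological condition flags) with full ground truth; noise-scaled
    threshold spike detection with stimulation-artifact blanking;
    stimulus-locked peristimulus time histograms; per-electrode evoked-response
    probabilities; direct-versus-synaptic response classification; conduction
    velocity estimation from inter-electrode spike latencies; and paired
    condition comparison with an exact Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
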