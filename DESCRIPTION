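Package: swdpredict
Title: Prediction of Spike-and-Wave Discharges from Multichannel LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wavelet-based prediction of spike-and-wave discharges (SWDs, the
    electrographic signature of absence seizures) from multichannel local
    field potential recordings in the cortico-thalamic system. Implements
    sliding-window Morlet band energies and their cross-channel products,
    three-criterion precursor detection with threshold and recording-site
    sweeps, onset marking and true/false-positive labeling against a 1-s
    preictal window, random-forest discrimination of true versus false alarms
    with under- and oversampling, permutation surrogate statistics, and an
    annotated synthetic LFP generator emulating GAERS- and WAG/Rij-like
    recordings so that every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
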