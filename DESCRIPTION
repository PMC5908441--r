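Package: septorhythm
Title: Brain-State, Oscillation and Spike-Train Analysis for Medial Septal Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of extracellular recordings from the medial septum and
    diagonal band in head-fixed behaving mice: segmentation of behavioral
    states from rotary-encoder speed, detection of network oscillations from
    local field potentials (theta periods and phase, mid-gamma troughs,
    sharp-wave ripples, large-amplitude irregular activity), burst and rate
    metrics of spike trains per behavioral state, circular statistics of
    spike-phase coupling, Poisson and shuffle tests of firing modulation
    during sharp-wave ripples, the four-criterion classification of
    rhythmically bursting theta-peak-coupled "orchid" cells, group-level
    statistics over cells, and an optical-fractionator stereological
    estimator. Includes a ground-truth-annotated synthetic session generator
    emulating the statistical structure of the recorded data, and a packaged
    reference table of published per-cell metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'behavior.R'
    'filters.R'
    'intervals.R'
    'io.R'
    'oscillations.R'
    'phaseCoupling.R'
    'pipeline.R'
    'plotting.R'
    'population.R'
    'spikeMetrics.R'
    'swrModulation.R'
    'synthetic.R'
    'utils.R'
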