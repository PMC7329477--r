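Package: assrpipe
Title: Simulation and Source-Level Analysis of 40 Hz Auditory
    Steady-State MEG Responses
Version: 0.1.0
Authors@R: person("assrpipe", "developers", role = c("aut", "cre"),
    email = "maintainers@assrpipe.org")
Description: Tools to simulate and analyse magnetoencephalographic (MEG)
    auditory steady-state responses (ASSR) to 40 Hz clicktrain stimuli.
    Includes a synthetic two-group study generator with bilateral
    auditory-cortex dipoles and ground-truth effect templates, an
    analytic spherical-conductor forward model for magnetometer and
    planar-gradiometer arrays, Butterworth band-pass/band-stop
    preprocessing with variance-based trial rejection, LCMV beamformer
    source localisation with region-of-interest virtual electrodes,
    DPSS multitaper time-frequency power and inter-trial coherence, and
    cluster-based permutation statistics for within- and between-group
    contrasts with brain-behaviour correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
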