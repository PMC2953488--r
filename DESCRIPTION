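Package: ringpmf
Title: Free-Energy Profiles and Sugar-Ring Puckering Itineraries from
    Umbrella-Sampling Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the mechanistic analysis of glycoside hydrolase
    reaction trajectories: evaluation of composite reaction coordinates and
    geometric monitors (distances, hydrogen bonds, ring-plane angles, Kabsch
    RMSD) on coordinate frames; reconstruction of one-dimensional potentials
    of mean force from harmonic umbrella-sampling windows by the weighted
    histogram analysis method (WHAM), with landmark extraction (stationary
    points, barrier, reaction free energy) and profile-to-profile spread;
    Cremer-Pople puckering coordinates, Stoddart projections and canonical
    conformer classification for six-membered sugar rings, with per-region
    itinerary summaries; and a desk-scale synthetic-data generator that
    samples an analytic landmark potential by overdamped Langevin dynamics
    and emits ring geometries tracing a prescribed conformational itinerary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
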