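Package: sptcrowd
Title: Single-Particle Tracking and Crowding Biophysics for Starvation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and quantification tools for studies of macromolecular
    mobility in yeast under glucose starvation. Provides generators for 2D
    Brownian, fractional-Brownian (subdiffusive) and confined (Ornstein-
    Uhlenbeck) trajectories with localization noise and synthetic spot movies;
    a centroid-based spot detector and optimal nearest-neighbour linker;
    per-trajectory and ensemble mean-square-displacement (MSD) analysis with
    effective diffusion coefficient (K, slope of the MSD over the first ten
    lags) and anomalous exponent (alpha, power-law fit over the first forty
    lags) estimation; two-locus intranuclear distance MSDs; and biophysical
    calculators for accessible cytoplasmic volume, Coulter-counter volume
    distributions, dry-mass crowding indices, AFM compression stiffness,
    ratiometric pH calibration, and luciferase ATP standardization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
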