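Package: membraneprobe
Title: Structural Analysis of Lipid Bilayers from Trajectories, SAXS, EPR and AFM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative post-processing for membrane-biophysics studies of
    dicarboxylic-acid aggregation and flavonoid interactions in phospholipid
    bilayers. Computes trajectory-derived structural statistics (leaflet
    assignment, number and electron density profiles, center-of-mass radial
    distribution functions, hydrogen-bond graphs and aggregate clustering,
    water penetration and water-wire detection, lateral inter-leaflet
    thickness maps), models and fits small-angle X-ray scattering curves with
    an error-function slab electron density profile and a modified Caille
    structure factor, derives spin-label EPR order parameters and rotational
    correlation times from hyperfine extrema, and post-processes atomic force
    microscopy force curves and height maps (breakthrough thickness, Hertz
    modulus, roughness). Ships seeded synthetic-data generators with planted
    ground truth so every stage is testable without instrument data, and a
    YAML-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
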