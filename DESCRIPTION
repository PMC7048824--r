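Package: noseflow
Title: Statistical Shape Modelling and Quasi-1D Airflow Analysis of Nasal
    Cavity Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Asks whether the airflow computed in an average nasal geometry
    equals the average of the airflows computed in the individual geometries
    it was built from.  Provides a generator of corresponded bilateral
    nasal-cavity-like duct geometries with known low-rank shape variation,
    principal-component statistical shape models over corresponded surface
    corpora with mirrored augmentation, a quasi-one-dimensional laminar flow
    model with the exact elliptical-duct viscous law and optional
    Borda-Carnot expansion losses, nearest-neighbour mapping of wall-bound
    fields onto a reference triangulation with vertex-wise statistics, and
    the integral aerodynamic measures used in rhinologic modelling work
    (lateral and total nasal resistance, airflow partitioning, averaged and
    99.9th-percentile velocity and wall shear stress, cross-sectional area
    profiles, wall-shear-stress surface histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
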