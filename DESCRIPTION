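Package: lnpmd
Title: Structure-Function Analysis of Lipid Nanoparticle Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trajectory-derived structural descriptors for ionizable-lipid
    bilayers and the statistics that link them to lipid nanoparticle (LNP)
    delivery performance. Implements per-lipid critical packing parameter
    estimation by two definitions (truncated-cone volume and planar radii
    of gyration), bilayer thickness, component density profiles, monolayer
    torque density from lateral pressure profiles, area compressibility
    from area fluctuations, and a bilayer-stability screen based on lipid
    escape events. Also provides molecular-graph tools for ionizable
    lipids (amine classification and rule-based protonation-site
    selection from SMILES), standardization of heterogeneous delivery
    readouts by per-publication, per-context z-scoring, and correlation
    analyses between simulated features and delivery readouts. A
    synthetic-data module generates bilayer trajectories with analytically
    known cone geometry, area time series, piecewise-analytic pressure
    profiles, and delivery datasets with prescribed correlation, so the
    whole pipeline is testable without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    pracma,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
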