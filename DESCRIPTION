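Package: vertexflux
Title: Stochastic Vertex Model of Epithelial Junction Dynamics and
    Neighbor-Exchange Analysis
Version: 0.1.0
Authors@R:
    person("vertexflux", "maintainers", email = "vertexflux@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-dimensional vertex model of an epithelial
    monolayer on a periodic box in which line tensions fluctuate as
    Ornstein-Uhlenbeck processes around per-junction reference tensions,
    triggering T1 neighbor-exchange events when junctions shrink below a
    threshold length.  Provides summary statistics for tissue packing
    (topological disorder, polygon-class fractions, junction-length
    variability), correlation analysis of tension and length time series,
    a tracking pipeline that reconstructs junctions, cells and T1 events
    from skeletonized segmentation movies (with fluorescence-intensity
    measurement, drift registration, persistence segments and
    reversibility survival curves), and generators for fully synthetic
    ground-truth movies and intensity traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
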