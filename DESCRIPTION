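Package: isozone
Title: Multivariate Isoscape Zoning of Plant-Invader Influence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps the zone of influence of a plant invader from georeferenced
    foliar tracer measurements (nitrogen concentration, delta-15N, delta-13C).
    Tracers are interpolated to per-plot isoscapes by ordinary kriging with
    variogram-model and lag-segmentation selection via leave-one-out
    cross-validation; the stacked isoscapes are partitioned into homogeneous
    zones by Gaussian mixture models with constrained covariance
    parameterizations (EM, BIC plateau selection); and zones are harmonized
    across plots by UPGMA clustering of zone medians with a silhouette-optimal
    cut. Includes a synthetic-plot generator with canopy-distance influence
    kernels and ground-truth zone labels, Kruskal-Wallis zone contrasts with a
    mean-rank post-hoc and compact letter display, plain-text raster and
    polygon I/O, and a configuration-driven pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    yaml,
    jsonlite,
    ape,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
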