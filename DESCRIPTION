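Package: asset17
Title: Automatic AHA 17-Segment Model of the Left Ventricle from Binary Masks
Version: 0.1.0
Authors@R:
    person("ASSET", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates the American Heart Association 17-segment model of the
    left-ventricular myocardium from a 3D binary left-ventricle mask and a
    single right-ventricle insertion point. The parasternal long axis is
    estimated as the first principal component of the mask voxel coordinates,
    the ventricle is split into basal, mid-cavitary, apical and apex regions by
    equally spaced short-axis planes, the basal/mid regions are divided into
    six 60-degree sectors and the apical region into four 90-degree sectors
    anchored at the RV insertion azimuth, and segment masks are post-processed
    by morphological closing. Includes Dice and mean-distance-to-agreement
    evaluation metrics, a prolate-spheroid phantom generator with analytic
    ground-truth labels, minimal NIfTI-1 input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
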