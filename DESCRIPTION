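Package: depca
Title: Principal Component Analysis for Designed Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Principal component analysis adapted to designed experiments
    with grouped, repeated measurements. Orthogonal axes are identified by
    singular value decomposition of training data built from group
    representatives (means, trimmed means or medians), the data are centered
    on an experiment-defined reference (control-group or grand mean), and
    component scores are scaled by the square root of the number of
    functional items (samples) or training rows (items) so that scores keep
    a size unit independent of how many items were measured. Axis models can
    be serialized and shared across experiments, and unknown samples can be
    classified by nearest group representative on pre-arranged axes.
    Includes a per-gene two-way ANOVA filter on probe-level data and a
    synthetic-data generator for group-structured expression experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
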