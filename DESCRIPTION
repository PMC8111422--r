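Package: prepctrl
Title: Optimal Anticipatory Control of Motor Preparation in Recurrent Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models movement preparation in motor cortex as optimal anticipatory
    control. Builds inhibition-stabilized and other recurrent rate networks that
    drive a planar two-link arm through a low-dimensional torque readout,
    calibrates movement-specific preparatory states, and derives preparatory
    feedback controllers: the classical linear quadratic regulator based on the
    observability Gramian of the motor readout, and biologically constrained
    variants (excitatory-only feedback, Dale-law sign structure, lagged
    thalamo-cortical loops gated by basal-ganglia disinhibition). Includes
    population-geometry analyses (participation ratio, alignment index, jPCA,
    canonical correlations, subspace potency), simulated photoinhibition
    experiments, and a synthetic firing-rate generator for standalone testing
    of the analysis metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse, Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
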