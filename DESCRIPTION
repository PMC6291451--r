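Package: narmaxhnn
Title: NARMAX System Identification with a Neuroanatomically Structured
    Hierarchical Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear system identification of closed-loop neural responses
    to periodic joint perturbations. Implements a NARMAX-framework model whose
    nonlinear function is a two-layer hierarchical sigmoid network with
    afferent-pathway delays (fast Ia and slow II input channels) and
    autoregressive feedback, trained by scaled conjugate gradient on
    mean-squared one-step error; polynomial NARMAX and Volterra baselines with
    orthogonal forward regression term selection by error-reduction ratio;
    one- to three-step-ahead predictors; variance-accounted-for scoring under
    leave-one-trial-out cross-validation; and a multisine stimulus and
    trial-structured synthetic-data generator so the whole pipeline runs
    without measured data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
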