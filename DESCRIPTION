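Package: tesmontage
Title: Multichannel Transcranial Electrical Stimulation Montage Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs safety-constrained multichannel transcranial electrical
    stimulation (tES/tDCS) montages with an L1-norm fitted and L1-norm
    penalized linear program over electrode currents. The regularization
    weight and nuisance-field threshold are tuned over a logarithmic (dB)
    hyperparameter lattice by exhaustive, direct (pattern), and recursive
    grid-refinement search, with a reciprocity-principle bipolar montage as
    the analytic intensity reference. Ships its own linear programming layer
    (Mehrotra predictor-corrector interior point, two-phase primal simplex,
    dual simplex) behind a uniform backend registry so algorithm classes can
    be compared on identical problems, and a synthetic spherical-head lead
    field generator so the whole pipeline runs without MRI or finite-element
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
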