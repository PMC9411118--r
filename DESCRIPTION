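Package: phoslim
Title: Phosphorus Constraints on Photosynthetic Capacity, from Leaf to Canopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying leaf-phosphorus constraints on
    photosynthesis. Implements the forward Farquhar-von Caemmerer-Berry
    (FvCB) model of C3 photosynthesis with peaked and Arrhenius temperature
    responses, nonlinear least-squares inversion of A-Ci curves for Vcmax,
    Jmax and Rd normalised to 25 degrees C, quality-control filters and
    species-at-site aggregation for gas-exchange compilations, the log-log
    OLS and standardised-major-axis regression framework used to relate
    photosynthetic biochemistry to leaf nitrogen and phosphorus (including
    separate-slopes and N x P interaction tests), published predictor
    equations for Vcmax and Jmax from leaf N and P on mass and area bases
    with a sigmoidal phosphorus-acquisition scalar, and a simplified
    big-leaf canopy engine that contrasts gross primary productivity under
    phosphorus-limited versus phosphorus-unlimited leaf stoichiometry.
    Includes synthetic-data generators that emulate the statistical
    structure of pan-tropical leaf trait datasets so the whole pipeline can
    be exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
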