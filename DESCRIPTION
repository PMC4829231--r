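Package: smeedfit
Title: Modified Smeed Models of Road Traffic Mortality and Motorization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling national road-traffic mortality as a
    function of motorization with the modified Smeed equation
    D/P = a (N/P) exp(-b N/P). The model is fitted in its log-linear form
    by ordinary least squares, with leverage, studentized-residual and
    Cook's distance diagnostics and a diagnose-exclude-refit outlier
    procedure. From a fitted model the package derives the predicted
    maximum mortality a/(e b), the motorization level 1/b at which the
    peak occurs, and the calendar period in which an observed motorization
    trajectory crosses that peak, and builds ranked cross-country
    comparison tables. A seeded synthetic-panel generator produces
    country-year data with the model's statistical structure for
    parameter-recovery and outlier-detection experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
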