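Package: lakescen
Title: Scenario Projection of Lake and Reservoir Eutrophication from
    Catchment Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts chlorophyll a of shallow lakes and reservoirs from
    catchment-scale descriptors (catchment-to-lake area ratio, land cover,
    drainage density, depth, altitude, season) with random-forest regression
    and classification models, and projects the response of mean chlorophyll a
    and eutrophic-state frequency to land-use and nutrient-load management
    scenarios on pressure-multiplier grids, stratified by drainage versus
    seepage lakes. Includes a calibrated synthetic lake-catchment generator,
    repeated-holdout validation with averaged R-squared and Cohen's kappa,
    response-surface slicing with saturating-versus-linear curve
    classification, recovery and compensation threshold finders, and a 2030
    nutrient-reduction / urbanisation policy scenario report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
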