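Package: abdoprofile
Title: Thoracic-Abdominal Profile Morphometrics with Quadratic Bezier Curves
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the thoracic-abdominal profile of a standing patient as two
    linked quadratic Bezier curves anchored on nine digitized landmarks, and
    derives the geometric adiposity parameters used in non-invasive screening
    for non-alcoholic fatty liver disease: curvatures and osculating radii at
    the extreme points, superior/inferior/total arc lengths, areas above and
    below the waist plane, the half solid-of-revolution volume of the lower
    belly, and the anterior/inferior projections.  Profiles are classified
    into raised/fallen, flat/prominent and advanced types from published
    interval thresholds, and composite A/B steatosis categories.  Includes a
    seeded synthetic-cohort generator with ultrasound liver diameters coupled
    linearly to the inferior arc length, the cohort statistical workflow
    (normality checks, Levene-gated t-tests, Pearson and partial correlations,
    simple linear regression, correlation power analysis), landmark CSV and
    two-segment quadratic SVG path ingest, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
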