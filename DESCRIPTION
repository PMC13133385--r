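Package: floatbias
Title: Diagnosing Systematic pH Bias in Biogeochemical Argo Float Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing a systematic bias in autonomous-float pH and
    derived pCO2 against ship-based reference data in the Southern Ocean. The
    package bundles a total-scale marine carbonate system solver with the
    Lueker/Dickson/Perez-Fraga/Lee constant set, anthropogenic-carbon
    back-calculation by the delta-C-star and TrOCA methods, water-mass screening
    for unacidified Circumpolar Deep Water, float-ship profile and level
    matching, the 1500-m crossover and pH-dependent float adjustments,
    carbon-and-oxygen-relative-to-saturation (CORS) surface analysis, Deming
    errors-in-variables regression, deviation-degree (Cohen's d) depth profiles,
    Monte Carlo uncertainty propagation, and air-sea flux scaling. A synthetic
    data generator emulates Southern Ocean water-column structure with a
    configurable injected float pH bias so the entire pipeline is testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
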