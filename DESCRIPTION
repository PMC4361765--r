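Package: ohindex
Title: Composite Ocean-Health Index Engine with Catch-Only Stock Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes composite ocean-health scores for coastal reporting
    regions from long-format data layers: per-goal current status, trend,
    pressure and resilience are combined into goal scores and a single
    0-100 Index. Includes a catch-only (catch-MSY) stock-assessment
    sub-model based on a Schaefer surplus-production model with
    resilience-switched depletion priors, the fisheries sub-goal
    (piecewise B/BMSY scoring, taxonomic-resolution penalties and
    catch-weighted geometric-mean aggregation), mariculture and
    tourism-and-recreation status models with percentile reference
    points, assessment comparison and goal-correlation reporting, and a
    seeded synthetic-data generator with known ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
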