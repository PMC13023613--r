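Package: sepsispanel
Title: Composite Marker-Gene-Panel Assessment of Immune Dysregulation in Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores bulk RNA-seq expression profiles against five canonical
    marker gene sets of the sepsis host response (neutrophil degranulation,
    type I and type II interferon signaling, MHC class II, and
    lymphocyte/dendritic-cell markers), computes the composite NDrG-HLAd
    score, and evaluates threshold decision rules for survivor
    identification, alone and combined with the SOFA score. Includes the
    cohort statistics used around such panels (Welch and paired t contrasts,
    Tukey HSD multi-group comparison, SOFA correlation, panel-level PCA),
    per-subject serial monitoring of dysregulation reversal in the ICU, and
    a negative-binomial synthetic-cohort generator calibrated to published
    effect sizes so the whole pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
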