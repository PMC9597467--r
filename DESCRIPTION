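Package: yamnue
Title: Nutrient Use Efficiency and Soil Fertility Susceptibility Analysis
    for Yam Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for split-plot fertilizer trials on white
    Guinea yam (Dioscorea rotundata) and similar root crops. Computes
    per-plant biomass traits (dry shoot weight, tuber dry matter content,
    dry tuber weight), organ-wise nitrogen, phosphorus and potassium
    uptake, and the standard nutrient-use-efficiency indices: percent
    difference between fertility levels, the soil fertility
    susceptibility index (SFSI), apparent nutrient recovery efficiency,
    and physiological efficiency, with genotype susceptibility
    classification. Includes classical trial statistics (per-genotype
    treatment contrasts, Tukey HSD with compact letter displays, Pearson
    correlation, split-plot ANOVA) and a calibrated synthetic-trial
    generator so every stage of the pipeline can be exercised without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
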