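Package: twosexlt
Title: Age-Stage Two-Sex Life Tables with Bootstrap Inference for Insect Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of age-stage, two-sex life tables from
    individual insect life-history records (daily census of stage durations,
    sex, fate and fecundity). Computes age-stage survival rates, age-specific
    survival and fecundity schedules, population growth parameters (intrinsic
    and finite rates of increase, net and gross reproduction rates, mean
    generation time) via the Euler-Lotka equation, age-stage life expectancy
    and reproductive value, and reproductive summaries (pre-oviposition
    periods, preadult survivorship, oviposition days). Standard errors are
    obtained by an individual-resampling bootstrap. Includes a calibrated
    cohort and endpoint simulator for dose-response study designs, an
    assumption-screened group-comparison procedure (ANOVA/Tukey or
    Kruskal-Wallis/Dunn-Holm), treatment-mean Pearson correlation analysis
    with heatmap export, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    car,
    jsonlite,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
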