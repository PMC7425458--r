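Package: survewas
Title: Epigenome-Wide Survival Meta-Analysis of DNA Methylation and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for epigenome-wide association studies of
    all-cause mortality in multi-cohort consortia: per-CpG Cox proportional
    hazards screening (direct and two-step residual variants), consortium-style
    probe quality-control filtering, inverse-variance fixed-effects
    meta-analysis with genomic-inflation, heterogeneity, leave-one-out and
    cohort-exclusion diagnostics, Miettinen's population attributable fraction,
    two-sample Mendelian randomization (Wald ratio, MR-Egger, weighted median,
    weighted mode), reference-based leukocyte deconvolution with
    neutrophil-lymphocyte-ratio mortality models, meQTL/eQTM integration,
    genomic-feature enrichment, and epigenetic-clock scoring.  Includes a
    synthetic multi-cohort data generator emulating 450K-style methylation,
    harmonized covariates, right-censored survival and GWAS summary statistics,
    so the whole pipeline is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    lme4,
    lmerTest,
    pracma
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
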