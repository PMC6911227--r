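Package: phemap
Title: Mapping ICD-10 and ICD-10-CM Diagnosis Codes to Phecodes for EHR
    Phenotyping and PheWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A provenance-tracked engine for translating ICD-10 and
    ICD-10-CM diagnosis codes to phecodes via direct description matching
    and indirect crosswalk chains (General Equivalence Mappings, UMLS CUI
    equivalences, SNOMED CT, NLM rule maps, and OHDSI concept
    relationships), with parent/child hierarchy resolution. Includes
    phecode-based case/control phenotyping with exclusion ranges,
    code-coverage accounting, two-window phenotype-reproducibility
    analysis, a per-phecode logistic-regression PheWAS with covariate
    adjustment, and a synthetic EHR simulator so the full workflow is
    testable without licensed terminology downloads or patient data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
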