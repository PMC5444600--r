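Package: admixSMR
Title: Subcontinental Ancestry Components and Disease-Specific Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised estimation of individual admixture proportions against
    fine-grained reference panels, genotype quality control, LD pruning,
    eigenstrat-style principal component analysis and Weir-Cockerham Fst,
    followed by a two-stage ecological regression that links expected regional
    ancestry components to disease-specific standardized mortality ratios per
    1 percent ancestry. Includes the sensitivity procedures of the underlying
    study design (leave-one-out influence on regional ancestry, resampling of
    regional ancestry estimates, ancestry-informative-marker selection by
    minor-allele-frequency confidence intervals, adjustment for additional
    regional covariates), an individual-level proportional-hazards validation
    stage, and a synthetic-data generator with known ground truth emulating a
    four-way admixed population with two closely related Native subcomponents.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    sandwich,
    MASS,
    nlme,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
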