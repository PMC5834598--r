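Package: lipoclass
Title: Chemometric Classification of Direct-Infusion Lipidomic Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two-class chemometric classification of untargeted
    direct-infusion electrospray-ionisation (ESI) lipidomic mass spectra,
    as used to discriminate blood plasma of healthy women (NILM) from
    women with cervical squamous intraepithelial lesions (SIL). Provides
    a seeded synthetic-cohort generator for centroided peak lists, common
    m/z axis construction across samples with their own mass axes,
    row-wise unit sum-of-squares normalisation, region-of-interest (ROI)
    intensity-threshold compression, deterministic Kennard-Stone sample
    splitting, feature reduction by principal component analysis or by a
    genetic algorithm minimising a Mahalanobis-distance misclassification
    risk, linear and quadratic discriminant classifiers, a soft-margin
    support vector machine with five kernels solved by sequential minimal
    optimisation, k-nearest-neighbour classification, evaluation by
    sensitivity, specificity, ROC AUC and the harmonic-mean F-score, and
    annotation of discriminant m/z features against a packaged lipid
    reference table with ppm mass errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
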