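Package: dielniche
Title: Diel Activity Niches, Rest, and Their Evolution in Fish Behavioural Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temporal activity niches from long-term
    video tracking of individually housed fish, and for analysing their
    evolution across a species radiation. Provides a background-subtraction
    tracking chain (percentile backgrounds, blob detection, despiking,
    smoothing), activity and rest metrics (movement thresholding, sliding
    60-s rest windows, 30-min binning, daily profiles, Fisher
    g-periodograms), PCA-based diel guild classification (diurnal, nocturnal,
    crepuscular, cathemeral) with Ward clustering and a variability rule, a
    phylogenetic comparative engine (Pagel's lambda, Blomberg's K and its
    multivariate extension, PGLS, phylogenetic ANOVA, phylogenetically
    corrected two-block PLS, BM/OU/EB model fitting with AICc, OU ancestral
    states, and Mk models including 'bridge' variants that forbid direct
    diurnal-nocturnal transitions), and a species-level allele-frequency GWAS
    from genotype likelihoods (Hardy-Weinberg posterior allele frequencies,
    paired GLM and PGLS association tests, variant filtering). Seeded
    synthetic-data generators produce every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    vcfR,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    nlme,
    Matrix,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
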