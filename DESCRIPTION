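Package: mutarch
Title: Mutation-Accumulation Analysis of Fitness-Component Genetic Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of two-environment mutation-accumulation
    (MA) experiments in budding yeast, from replicate-level fitness observations to
    mutation rates and effect-size distributions. Implements per-generation changes
    in trait means and variances relative to an unmutated ancestor (delta-M, V_m,
    delta-V_E, mutational heritability), ancestor pseudo-line bootstrap inference,
    Steel-type many-to-one line tests, nested REML variance components for
    tetrad-derived haploids with likelihood-ratio tests, bivariate REML mutational
    genetic correlations, M-matrix assembly with random-skewers comparison and
    maximum evolvability, Bateman-Mukai moment estimators, a Poisson-gamma
    maximum-likelihood model of mutation number and effects with profile-likelihood
    confidence intervals, dominance estimation from diploid and derived-haploid
    declines, sliding-window growth-curve reduction, and a forward simulator of the
    full MA design (Poisson mutation counts, reflected-gamma effects, 2:2 tetrad
    segregation) so every stage is testable without raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
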