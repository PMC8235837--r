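Package: peelrec
Title: Pedigree-Based Recombination Rate Estimation by Multilocus Iterative Peeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates meiotic recombination counts and sex-specific genetic
    maps from pedigree and SNP-array genotype data by multilocus iterative
    peeling. Genotype probabilities are propagated through the pedigree via
    anterior (parental), penetrance (own data) and posterior (offspring)
    factors, and the inheritance of each parental haplotype along a chromosome
    is modelled as a two-state Markov chain whose smoothed posterior yields
    expected crossover counts per marker interval. Chromosome map length is
    refined iteratively from a 100 cM prior. Includes post-estimation quality
    filters, windowed recombination-landscape summaries, a gamete-dropping
    simulator with designed sex-specific landscapes and mixed-density
    genotyping for validation, and truncation-selection response calculators
    for recombination rate as a quantitative trait.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
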