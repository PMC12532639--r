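Package: strpopgen
Title: Forensic Parameters and Population Genetics for Autosomal STR Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads tab-delimited diploid autosomal short tandem repeat (STR)
    genotype tables (sample ID, population ID, two allele columns per locus,
    point alleles supported), computes allele and genotype frequency tables
    per population or pooled, performs the exact Hardy-Weinberg test
    (complete enumeration of genotype configurations conditional on allele
    counts when feasible, permutation Monte Carlo otherwise, with Bonferroni
    adjustment), derives the standard forensic parameters per locus and
    combined (observed/expected heterozygosity, polymorphism information
    content, probability of match, power of discrimination, power of
    exclusion, typical paternity index), and builds pairwise Nei D_A and
    expected-homozygosity F_st distance matrices between populations. A
    seeded synthetic-population generator produces genotype tables with
    known allele frequencies, inbreeding and missingness for validation, and
    a small command-line front end exports all tables as TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
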