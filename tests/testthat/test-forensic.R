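freqs_table <- function(...) {
  # build an str_allele_freqs from exact genotype compositions
  allele_frequencies(table_from_composition(...))
}

test_that("closed-form spot checks for PIC, PE, TPI and He", {
  # PIC for p = (0.5, 0.5) and p = (0.25 x 4), via exact compositions
  f2 <- freqs_table(list(P = list(L = list(c("8", "9")))))
  expect_equal(pic(f2, "L", "P"), 0.375)
  f4 <- freqs_table(list(P = list(L = list(c("8", "9"), c("10", "11")))))
  expect_equal(pic(f4, "L", "P"), 0.703125)
  # monomorphic marker is uninformative
  f1 <- freqs_table(list(P = list(L = list(c("8", "8")))))
  expect_equal(pic(f1, "L", "P"), 0)
  expect_equal(power_of_exclusion(0.5, 0.5), 0.1875)
  expect_equal(power_of_exclusion(1, 0), 1)
  expect_equal(power_of_exclusion(0, 1), 0)
  expect_equal(typical_paternity_index(0.25), 2)
  expect_equal(typical_paternity_index(0.5), 1)
  expect_warning(v <- typical_paternity_index(0), "infinite")
  expect_identical(v, Inf)
  # He averages per-locus gene diversities: (0.5 + 0.375)/2
  fh <- freqs_table(list(P = list(
    LA = list(c("8", "9"), c("8", "9"), c("8", "9"), c("8", "9")),
    LB = list(c("8", "8"), c("8", "8"), c("8", "9"), c("8", "9")))))
  expect_equal(expected_heterozygosity(fh, "LA", "P"), 0.5)
  expect_equal(expected_heterozygosity(fh, "LB", "P"), 0.375)
  expect_equal(expected_heterozygosity(fh, c("LA", "LB"), "P"), 0.4375)
})

test_that("observed heterozygosity counts heterozygous typed individuals", {
  t <- table_from_composition(list(P = list(L = list(
    c("12", "13"), c("12", "12"), c(NA, NA)))))
  expect_equal(observed_heterozygosity(t, "L", "P"), 0.5)
  t_hom <- table_from_composition(list(P = list(L = list(
    c("12", "12"), c("13", "13")))))
  expect_equal(observed_heterozygosity(t_hom, "L", "P"), 0)
  t_het <- table_from_composition(list(P = list(L = list(
    c("12", "13"), c("12", "14")))))
  expect_equal(observed_heterozygosity(t_het, "L", "P"), 1)
})

test_that("match probability uses observed genotype frequencies", {
  t <- table_from_composition(list(P = list(L = list(
    c("12", "12"), c("12", "12"), c("12", "13"), c("13", "14")))))
  g <- genotype_frequencies(t)
  expect_equal(match_probability(g, "L", "P"), 0.375)  # .25+.0625+.0625
  expect_equal(power_of_discrimination(0.375), 0.625)
  # n all-distinct genotypes -> PM = 1/n
  t2 <- table_from_composition(list(P = list(L = list(
    c("8", "9"), c("10", "11"), c("12", "13")))))
  expect_equal(match_probability(genotype_frequencies(t2), "L", "P"), 1 / 3)
  # single genotype -> PM = 1
  t3 <- table_from_composition(list(P = list(L = list(c("8", "9")))))
  expect_equal(match_probability(genotype_frequencies(t3), "L", "P"), 1)
})

test_that("combining across loci follows the product and 1-prod(1-x) rules", {
  per <- data.frame(locus = c("A", "B"),
                    Ho = c(0.5, 0.5), He = c(0.5, 0.375),
                    PM = c(0.1, 0.1), PD = c(0.9, 0.9),
                    PE = c(0.5, 0.5), TPI = c(1, 2))
  comb <- combine_forensic(per)$combined
  expect_equal(comb[["PE"]], 0.75)
  expect_equal(comb[["PM"]], 0.01)
  expect_equal(comb[["PD"]], 0.99)
  expect_equal(comb[["PD"]], 1 - comb[["PM"]])  # exact identity
  expect_equal(comb[["Ho"]], 0.25)
  expect_equal(comb[["TPI"]], 2)
  # mean mode only changes Ho and He
  comb_m <- combine_forensic(per, combined_het = "mean")$combined
  expect_equal(comb_m[["Ho"]], 0.5)
  expect_equal(comb_m[["He"]], 0.4375)
  expect_equal(comb_m[["PM"]], comb[["PM"]])
  # single locus: combined equals the per-locus values
  one <- combine_forensic(per[1, ])$combined
  expect_equal(unname(one[c("Ho", "He", "PM", "PD", "PE", "TPI")]),
               unname(unlist(per[1, c("Ho", "He", "PM", "PD", "PE", "TPI")])))
})

test_that("summary table obeys the algebraic invariants on simulated data", {
  set.seed(71)
  t <- simulate_dataset(list(random_spec("P1", n = 40),
                             random_spec("P2", n = 30)))
  fs <- forensic_summary(t)
  per <- fs[fs$locus != "Combined", ]
  per <- per[!is.na(per$Ho), ]
  expect_equal(per$Ho + per$Hom, rep(1, nrow(per)))
  expect_equal(per$PM + per$PD, rep(1, nrow(per)))
  expect_true(all(per$PIC <= per$He + 1e-12))
  expect_true(all(per$He >= 0 & per$He <= 1))
  expect_true(all(per$PM >= 1 / per$n - 1e-12))
  comb <- fs[fs$locus == "Combined", ]
  for (g in comb$group) {
    pg <- per[per$group == g, ]
    expect_equal(comb$PD[comb$group == g], 1 - prod(pg$PM))
    expect_equal(comb$PM[comb$group == g], prod(pg$PM))
    expect_true(is.na(comb$PIC[comb$group == g]))
  }
})

test_that("appending loci never decreases combined PD/PE or increases PM", {
  set.seed(72)
  t <- simulate_dataset(list(random_spec("P1", n = 30, n_loci = 5,
                                         missing_rate = 0)))
  fs <- forensic_summary(t)
  per <- fs[fs$locus != "Combined", ]
  prev <- NULL
  for (k in seq_len(nrow(per))) {
    comb <- combine_forensic(per[seq_len(k), ])$combined
    if (!is.null(prev)) {
      expect_lte(comb[["PM"]], prev[["PM"]] + 1e-12)
      expect_gte(comb[["PD"]], prev[["PD"]] - 1e-12)
      expect_gte(comb[["PE"]], prev[["PE"]] - 1e-12)
    }
    prev <- comb
  }
})

test_that("grouping modes produce the expected row sets", {
  set.seed(73)
  t <- simulate_dataset(list(random_spec("P1", n = 20, missing_rate = 0),
                             random_spec("P2", n = 20, missing_rate = 0)))
  fs_pop <- forensic_summary(t)
  expect_equal(sum(fs_pop$locus == "Combined"), 2)
  fs_pool <- forensic_summary(t, "pooled")
  expect_equal(sum(fs_pool$locus == "Combined"), 1)
  expect_equal(unique(fs_pool$group), "all")
  # per-locus values equal the component operations called directly
  f <- allele_frequencies(t); g <- genotype_frequencies(t)
  loc <- t$loci[1]
  row <- fs_pop[fs_pop$group == "P1" & fs_pop$locus == loc, ]
  expect_equal(row$Ho, observed_heterozygosity(t, loc, "P1"))
  expect_equal(row$He, expected_heterozygosity(f, loc, "P1"))
  expect_equal(row$PIC, pic(f, loc, "P1"))
  expect_equal(row$PM, match_probability(g, loc, "P1"))
  expect_equal(row$PE, power_of_exclusion(row$Ho, row$Hom))
})
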