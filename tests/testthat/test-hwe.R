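test_that("configuration probability matches hand-evaluated values", {
  # n = 5, allele counts 5/5, all five heterozygous: 5!5!5!2^5/(10!·5!)
  c_het <- hwe_config("10", "11", 5)
  expect_equal(configuration_probability(c_het), 32 / 252, tolerance = 1e-12)
  # same allele counts, genotypes AA:2 AB:1 BB:2
  c_mix <- hwe_config(c("10", "10", "11"), c("10", "11", "11"), c(2, 1, 2))
  expect_equal(configuration_probability(c_mix), 60 / 252, tolerance = 1e-12)
  # monomorphic: only one configuration exists
  c_mono <- hwe_config("9", "9", 7)
  expect_equal(configuration_probability(c_mono), 1)
  expect_equal(hwe_exact(c_mono)$p_value, 1)
})

test_that("enumeration p-values match the worked two-allele case", {
  expect_equal(hwe_exact(hwe_config("10", "11", 5))$p_value, 32 / 252,
               tolerance = 1e-12)
  c_one_het <- hwe_config(c("10", "10", "11"), c("10", "11", "11"),
                          c(2, 1, 2))
  expect_equal(hwe_exact(c_one_het)$p_value, 92 / 252, tolerance = 1e-12)
})

test_that("enumeration agrees with the distinguishable-copy pairing oracle", {
  cases <- list(
    c("8", "8", "9", "9", "9", "9"),
    c("8", "9", "9", "10", "10", "10"),
    c("9.3", "9.3", "10", "10", "10", "10", "11", "11"),
    c("7", "7", "7", "7", "8", "8", "9", "9"),
    c("8", "8", "8", "9", "9", "9", "10", "10", "10", "10"))
  for (alleles in cases) {
    dist <- oracle_pairing_dist(alleles)
    expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
    for (key in dist$key) {
      pairs <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], "/")
      cfg <- hwe_config(vapply(pairs, `[`, "", 1L),
                        vapply(pairs, `[`, "", 2L),
                        rep(1L, length(pairs)))
      # each configuration's probability, and the p-value treating it as
      # the observed table, must match the matching-count fractions
      p_pkg <- configuration_probability(cfg)
      expect_equal(p_pkg, dist$prob[dist$key == key], tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(hwe_exact(cfg)$p_value,
                   oracle_pairing_p(alleles, key), tolerance = 1e-9)
    }
  }
})

test_that("enumeration agrees with the loop-based oracle on 3-allele tables", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    counts <- as.integer(table(factor(sample(1:3, 2 * n, replace = TRUE),
                                      levels = 1:3)))
    if (any(counts == 0)) counts <- counts[counts > 0]
    d <- oracle_loop_configs(counts)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    pick <- sample(nrow(d), min(5, nrow(d)))
    for (i in pick) {
      pairs <- strsplit(strsplit(d$key[i], ";", fixed = TRUE)[[1]], "/")
      cfg <- hwe_config(vapply(pairs, `[`, "", 1L),
                        vapply(pairs, `[`, "", 2L), rep(1L, length(pairs)))
      expect_equal(hwe_exact(cfg)$p_value, oracle_loop_p(counts, d$key[i]),
                   tolerance = 1e-9)
    }
  }
})

test_that("two-allele enumeration matches the Levene closed form", {
  # P(h heterozygotes | nA, nB) = n! nA! nB! 2^h /
  #   ((2n)! ((nA-h)/2)! h! ((nB-h)/2)!) for h with the parity of nA
  levene <- function(h, nA, nB) {
    n <- (nA + nB) / 2
    exp(lfactorial(n) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n) +
          h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((nB - h) / 2))
  }
  for (nA in c(3, 4, 7)) {
    nB <- 14 - nA
    hs <- seq(nA %% 2, min(nA, nB), by = 2)
    probs <- vapply(hs, levene, 1, nA, nB)
    expect_equal(sum(probs), 1, tolerance = 1e-9)
    for (h in hs) {
      cfg <- hwe_config(c("10", "10", "11"), c("10", "11", "11"),
                        c((nA - h) / 2, h, (nB - h) / 2))
      p_obs <- levene(h, nA, nB)
      expect_equal(hwe_exact(cfg)$p_value,
                   sum(probs[probs <= p_obs * (1 + 1e-9)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("Monte Carlo converges to the enumeration p and is seed-deterministic", {
  cfg <- hwe_config(c("10", "10", "11"), c("10", "11", "11"), c(6, 2, 7))
  p_enum <- hwe_exact(cfg)$p_value
  set.seed(99)
  r1 <- hwe_mc(cfg, replicates = 10000)
  expect_lt(abs(r1$p_value - p_enum), 3 * r1$mc_se)
  set.seed(99)
  r2 <- hwe_mc(cfg, replicates = 10000)
  expect_identical(r1$p_value, r2$p_value)
  # monomorphic locus: p = 1 for any seed
  set.seed(7)
  expect_equal(hwe_mc(hwe_config("9", "9", 60), replicates = 200)$p_value, 1)
})

test_that("the all-heterozygote sample n=10 matches brute-force enumeration", {
  cfg <- hwe_config("10", "20", 10)  # labels match the loop oracle's
  expect_equal(hwe_exact(cfg)$p_value,
               oracle_loop_p(c(10L, 10L), config_key(cfg)), tolerance = 1e-9)
})

test_that("hwe_test applies Bonferroni per group and flags untestable loci", {
  t <- table_from_composition(list(P1 = list(
    A = list(c("8", "9"), c("8", "9"), c("8", "8"), c("9", "9")),
    B = list(c("10", "11"), c("10", "10"), c("11", "11"), c("10", "11")),
    C = list(c("7", "7"), c(NA, NA), c(NA, NA), c(NA, NA)))))
  res <- hwe_test(t, seed = 5)
  expect_equal(nrow(res), 3)
  testable <- res[res$method != "untestable", ]
  expect_equal(testable$p_bonferroni, pmin(1, testable$p_value * 2))
  expect_equal(res$method[res$locus == "C"], "untestable")
  expect_true(is.na(res$p_value[res$locus == "C"]))
})

test_that("hwe_test falls back to Monte Carlo when enumeration exceeds budget", {
  set.seed(12)
  t <- simulate_population(population_spec(
    "P1", 80, list(L1 = stats::setNames(rep(0.125, 8), as.character(5:12)))))
  res <- hwe_test(t, replicates = 2000, seed = 3, enum_budget = 1000)
  expect_equal(res$method, "monte_carlo")
  expect_equal(res$replicates, 2000L)
  expect_gt(res$mc_se, 0)
  res2 <- hwe_test(t, replicates = 2000, seed = 3, enum_budget = 1000)
  expect_identical(res$p_value, res2$p_value)
})

test_that("p-values under a Hardy-Weinberg simulation are conservative", {
  # small-scale calibration: 150 loci, n = 50, 3 equifrequent alleles
  freqs <- rep(list(stats::setNames(rep(1 / 3, 3), c("8", "9", "10"))), 150)
  names(freqs) <- paste0("L", 1:150)
  t <- simulate_population(population_spec("P1", 50, freqs), seed = 61)
  res <- hwe_test(t, replicates = 2000, seed = 62)
  rate <- mean(res$p_value <= 0.05)
  expect_lte(rate, 0.08)  # nominal 0.05 plus binomial noise at 150 loci
  # p-value distribution stochastically >= uniform: conservative test
  expect_gte(mean(res$p_value > 0.5), 0.45)
})
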