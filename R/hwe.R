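#' Genotype count configuration for the exact Hardy-Weinberg test
#'
#' The exact test conditions on the observed allele counts; everything it
#' needs from the data is the table of genotype counts at one locus in one
#' group. Allele counts are derived from the genotype counts so the
#' configuration is internally consistent by construction.
#'
#' @param allele1,allele2 character vectors: the two alleles of each observed
#'   genotype class (unordered; canonicalized and reordered internally).
#' @param count integer vector of individuals per genotype class.
#' @param locus,group optional labels carried through to results.
#' @return an object of class `hwe_config` with fields `n` (individuals),
#'   `alleles` (labels, numeric order), `allele_counts` (named, sums to 2n),
#'   `genotype_counts` (data frame `allele1`, `allele2`, `count`), and `het`
#'   (number of heterozygous individuals).
#' @examples
#' hwe_config(c("10", "10"), c("10", "11"), c(3, 4))
#' @export
hwe_config <- function(allele1, allele2, count, locus = NA_character_,
                       group = NA_character_) {
  allele1 <- canonicalize_allele(allele1)
  allele2 <- canonicalize_allele(allele2)
  count <- as.integer(count)
  stopifnot(length(allele1) == length(allele2),
            length(allele1) == length(count))
  if (any(count < 0)) stop("negative genotype count", call. = FALSE)
  keep <- count > 0L
  allele1 <- allele1[keep]; allele2 <- allele2[keep]; count <- count[keep]
  swap <- allele_numeric(allele1) > allele_numeric(allele2)
  tmp <- allele1[swap]; allele1[swap] <- allele2[swap]; allele2[swap] <- tmp
  key <- paste(allele1, allele2, sep = "/")
  if (anyDuplicated(key)) {
    agg <- tapply(count, key, sum)
    parts <- strsplit(names(agg), "/", fixed = TRUE)
    allele1 <- vapply(parts, `[`, "", 1L)
    allele2 <- vapply(parts, `[`, "", 2L)
    count <- as.integer(agg)
  }
  alleles <- sort_alleles(unique(c(allele1, allele2)))
  ac <- stats::setNames(integer(length(alleles)), alleles)
  for (i in seq_along(count)) {
    ac[allele1[i]] <- ac[allele1[i]] + count[i]
    ac[allele2[i]] <- ac[allele2[i]] + count[i]
  }
  structure(list(
    locus = locus, group = group,
    n = sum(count), alleles = alleles, allele_counts = ac,
    genotype_counts = data.frame(allele1 = allele1, allele2 = allele2,
                                 count = count, stringsAsFactors = FALSE),
    het = sum(count[allele1 != allele2])),
    class = "hwe_config")
}

#' Extract a genotype configuration from a genotype table
#'
#' @param t a [genotype_table].
#' @param locus locus name.
#' @param group population label, or `NULL` to pool all samples.
#' @return an [hwe_config] over the typed individuals.
#' @export
locus_config <- function(t, locus, group = NULL) {
  stopifnot(inherits(t, "genotype_table"), locus %in% t$loci)
  sel <- if (is.null(group)) rep(TRUE, n_samples(t)) else
    t$population_id == group
  a1 <- t$a1[sel, locus]; a2 <- t$a2[sel, locus]
  typed <- !is.na(a1)
  if (!any(typed))
    return(structure(list(locus = locus,
                          group = if (is.null(group)) POOLED_LABEL else group,
                          n = 0L, alleles = character(),
                          allele_counts = integer(),
                          genotype_counts = data.frame(
                            allele1 = character(), allele2 = character(),
                            count = integer()),
                          het = 0L), class = "hwe_config"))
  key <- paste(a1[typed], a2[typed], sep = "/")
  tab <- table(key)
  parts <- strsplit(names(tab), "/", fixed = TRUE)
  hwe_config(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
             as.integer(tab), locus = locus,
             group = if (is.null(group)) POOLED_LABEL else group)
}

# configuration-dependent part of the log conditional probability
config_stat <- function(c) {
  c$het * log(2) - sum(lfactorial(c$genotype_counts$count))
}

#' Conditional probability of a genotype configuration given allele counts
#'
#' Probability of observing genotype counts `n_ij` among all ways of pairing
#' the fixed multiset of 2n allele copies into n diploid genotypes:
#' `n! * prod(n_i!) * 2^H / ((2n)! * prod(n_ij!))`, with `n_i` the allele
#' counts and `H` the number of heterozygous individuals. This is the null
#' distribution the exact Hardy-Weinberg test sums over.
#'
#' @param c an [hwe_config].
#' @return the probability (computed in log space).
#' @examples
#' # 5 individuals, all heterozygous 10/11 (allele counts 5 and 5): 32/252
#' configuration_probability(hwe_config("10", "11", 5))
#' @export
configuration_probability <- function(c) {
  stopifnot(inherits(c, "hwe_config"))
  if (c$n == 0L) return(1)
  logp <- lfactorial(c$n) + sum(lfactorial(c$allele_counts)) -
    lfactorial(2 * c$n) + config_stat(c)
  exp(logp)
}

hwe_result <- function(c, p, method, replicates = 0L, mc_se = 0,
                       n_configs = NA_real_) {
  list(locus = c$locus, group = c$group, n = c$n,
       k = length(c$alleles), p_value = p, method = method,
       replicates = replicates, mc_se = mc_se, n_configs = n_configs)
}

#' Exact Hardy-Weinberg p-value by complete enumeration
#'
#' Enumerates every genotype configuration compatible with the observed
#' allele counts and sums the probabilities of those no more probable than
#' the observed one (standard exact-test ordering). The full distribution is
#' checked to sum to 1. When the number of configurations exceeds `budget`
#' the function returns `NULL` so the caller can fall back to Monte Carlo.
#'
#' @param c an [hwe_config].
#' @param budget maximum number of configurations to visit.
#' @return a list (`locus`, `group`, `n`, `k`, `p_value`,
#'   `method = "enumeration"`, `replicates = 0`, `mc_se = 0`, `n_configs`),
#'   or `NULL` when the budget is exceeded.
#' @export
hwe_exact <- function(c, budget = 1e6) {
  stopifnot(inherits(c, "hwe_config"))
  if (c$n == 0L) return(hwe_result(c, NA_real_, "untestable"))
  res <- hwe_enum_cpp(as.integer(c$allele_counts), config_stat(c), budget)
  if (isTRUE(res$exceeded)) return(NULL)
  if (abs(res$total - 1) > 1e-9)
    stop("enumeration did not normalize (sum = ", res$total, ")",
         call. = FALSE)
  hwe_result(c, min(res$p, 1), "enumeration", n_configs = res$n_configs)
}

#' Exact Hardy-Weinberg p-value by permutation Monte Carlo
#'
#' Each replicate shuffles the multiset of 2n observed allele copies and
#' re-pairs consecutive copies into n genotypes, sampling from the same null
#' as the enumeration. The p-value uses the add-one correction
#' `(1 + hits) / (replicates + 1)` so it is never exactly 0. Driven by R's
#' RNG: call `set.seed()` (or use the `seed` argument of [hwe_test()]) for
#' reproducibility.
#'
#' @param c an [hwe_config].
#' @param replicates number of permutation replicates (>= 100).
#' @return a list as in [hwe_exact()] with `method = "monte_carlo"`,
#'   `replicates`, and the Monte-Carlo standard error
#'   `mc_se = sqrt(p*(1-p)/replicates)`.
#' @export
hwe_mc <- function(c, replicates = 10000L) {
  stopifnot(inherits(c, "hwe_config"), replicates >= 100L)
  if (c$n == 0L) return(hwe_result(c, NA_real_, "untestable"))
  codes <- rep(seq_along(c$alleles) - 1L, times = as.integer(c$allele_counts))
  hits <- hwe_mc_cpp(as.integer(codes), config_stat(c),
                     as.integer(replicates))
  p <- (1 + hits) / (replicates + 1)
  hwe_result(c, p, "monte_carlo", replicates = as.integer(replicates),
             mc_se = sqrt(p * (1 - p) / replicates))
}

#' Exact Hardy-Weinberg test across loci and groups
#'
#' Runs the exact test for every (locus, group) pair: complete enumeration
#' when the number of configurations is within `enum_budget`, permutation
#' Monte Carlo otherwise. Loci with fewer than 2 typed individuals are
#' flagged untestable and excluded from the Bonferroni count. Bonferroni
#' adjustment multiplies each p-value by the number of testable loci within
#' its group (capped at 1).
#'
#' @param t a [genotype_table].
#' @param grouping `"population"` or `"pooled"`.
#' @param replicates Monte-Carlo replicates for loci too large to enumerate.
#' @param seed optional integer seed (set once, before all loci).
#' @param enum_budget maximum configurations for complete enumeration.
#' @return data frame of class `str_hwe` with one row per (locus, group):
#'   `locus`, `group`, `n`, `k`, `p_value`, `method`, `replicates`, `mc_se`,
#'   `p_bonferroni`.
#' @examples
#' t <- simulate_population(population_spec("P1", 40,
#'   list(L1 = c(`8` = 0.5, `9` = 0.5))), seed = 7)
#' hwe_test(t)
#' @export
hwe_test <- function(t, grouping = c("population", "pooled"),
                     replicates = 10000L, seed = NULL, enum_budget = 1e6) {
  stopifnot(inherits(t, "genotype_table"))
  grouping <- match.arg(grouping)
  if (!is.null(seed)) set.seed(seed)
  groups <- if (grouping == "population") populations(t) else POOLED_LABEL
  rows <- list()
  for (g in groups) {
    gres <- list()
    for (loc in t$loci) {
      c <- locus_config(t, loc, if (grouping == "population") g else NULL)
      if (c$n < 2L) {
        gres[[loc]] <- hwe_result(c, NA_real_, "untestable")
        next
      }
      r <- hwe_exact(c, budget = enum_budget)
      if (is.null(r)) r <- hwe_mc(c, replicates = replicates)
      gres[[loc]] <- r
    }
    m <- sum(vapply(gres, function(r) r$method != "untestable", TRUE))
    for (r in gres) {
      r$p_bonferroni <- if (r$method == "untestable") NA_real_ else
        min(1, r$p_value * m)
      r$n_configs <- NULL
      rows[[length(rows) + 1L]] <- as.data.frame(r,
                                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("str_hwe", "data.frame")
  out
}
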