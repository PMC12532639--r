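#' Observed heterozygosity at a locus
#'
#' Proportion of typed individuals that are heterozygous.
#'
#' @param t a [genotype_table].
#' @param locus locus name.
#' @param group population label, or `NULL` to pool all samples.
#' @return proportion in \[0, 1\]; `NA` when no individual is typed.
#' @export
observed_heterozygosity <- function(t, locus, group = NULL) {
  stopifnot(inherits(t, "genotype_table"), locus %in% t$loci)
  sel <- if (is.null(group)) rep(TRUE, n_samples(t)) else
    t$population_id == group
  a1 <- t$a1[sel, locus]; a2 <- t$a2[sel, locus]
  typed <- !is.na(a1)
  if (!any(typed)) return(NA_real_)
  mean(a1[typed] != a2[typed])
}

#' Expected heterozygosity (gene diversity)
#'
#' Per locus, `1 - sum(p_i^2)` over the allele frequencies; for several loci
#' the arithmetic mean of the per-locus values. No small-sample bias
#' correction is applied.
#'
#' @param f an `str_allele_freqs` table.
#' @param loci locus names; `NULL` for all loci typed in the group.
#' @param group group label (a population, or `"all"` for pooled tables).
#' @return mean gene diversity over the requested loci; untyped loci are
#'   dropped with a warning.
#' @export
expected_heterozygosity <- function(f, loci = NULL, group) {
  stopifnot(inherits(f, "str_allele_freqs"))
  sizes <- freq_sizes(f)
  if (is.null(loci)) loci <- unique(sizes$locus[sizes$group == group])
  vals <- numeric(0)
  for (loc in loci) {
    p <- allele_freq_vector(f, loc, group)
    if (!length(p)) {
      warning("locus ", loc, " untyped in group ", group, "; dropped",
              call. = FALSE)
      next
    }
    vals <- c(vals, 1 - sum(p^2))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`: the probability that a
#' marker is informative in a linkage/kinship setting. Always `<=` the gene
#' diversity of the same frequencies.
#'
#' @inheritParams expected_heterozygosity
#' @param locus locus name.
#' @return PIC value in \[0, 1\]; `NA` when the locus is untyped.
#' @export
pic <- function(f, locus, group) {
  p <- allele_freq_vector(f, locus, group)
  if (!length(p)) return(NA_real_)
  p2 <- p^2
  cross <- (sum(p2)^2 - sum(p2^2)) / 2  # sum_{i<j} p_i^2 p_j^2
  1 - sum(p2) - 2 * cross
}

#' Probability of match at a locus
#'
#' `PM = sum(g_i^2)` over the OBSERVED genotype frequencies `g_i` — the
#' probability that two individuals drawn from the sample share a genotype.
#' Hardy-Weinberg expected genotype frequencies are deliberately not used.
#'
#' @param g an `str_genotype_freqs` table.
#' @param locus,group names identifying the cell.
#' @return probability in \[1/n, 1\]; `NA` when the locus is untyped.
#' @export
match_probability <- function(g, locus, group) {
  stopifnot(inherits(g, "str_genotype_freqs"))
  sub <- g[g$locus == locus & g$group == group, ]
  if (!nrow(sub)) return(NA_real_)
  sum(sub$frequency^2)
}

#' Power of discrimination
#'
#' @param pm probability of match.
#' @return `1 - pm`.
#' @export
power_of_discrimination <- function(pm) {
  stopifnot(all(is.na(pm) | (pm >= 0 & pm <= 1)))
  1 - pm
}

#' Power of exclusion
#'
#' `PE = h^2 * (1 - 2*h*H^2)` with `h` the proportion of heterozygous and
#' `H` the proportion of homozygous individuals (h + H = 1). Proportions,
#' not counts: the count form is unbounded and does not give a probability.
#'
#' @param h proportion of heterozygous individuals.
#' @param hom proportion of homozygous individuals (`1 - h`).
#' @return exclusion probability in \[0, 1\].
#' @export
power_of_exclusion <- function(h, hom = 1 - h) {
  stopifnot(all(is.na(h) | abs(h + hom - 1) < 1e-9))
  h^2 * (1 - 2 * h * hom^2)
}

#' Typical paternity index
#'
#' `TPI = 1 / (2 * H)` with `H` the proportion of homozygous individuals.
#' When every individual is heterozygous (`H = 0`) the index is infinite;
#' this is reported as `Inf` with a warning rather than an error.
#'
#' @param hom proportion of homozygous individuals.
#' @return paternity index (>= 0.5, possibly `Inf`).
#' @export
typical_paternity_index <- function(hom) {
  stopifnot(all(is.na(hom) | (hom >= 0 & hom <= 1)))
  out <- ifelse(hom == 0, Inf, 1 / (2 * hom))
  if (any(!is.na(out) & is.infinite(out)))
    warning("no homozygotes observed; typical paternity index is infinite",
            call. = FALSE)
  out
}

#' Combine per-locus forensic parameters across loci
#'
#' Ho, He, PM and TPI combine by multiplying the per-locus values; PE and PD
#' combine as `1 - prod(1 - x_i)`. Because `PD_i = 1 - PM_i` per locus, the
#' combined PD equals `1 - prod(PM_i)` exactly. PIC has no combined form.
#' `combined_het = "mean"` replaces the product-combined Ho and He with
#' their arithmetic means (the convention in most published tables).
#'
#' @param per_locus data frame with columns `locus`, `Ho`, `He`, `PM`, `PD`,
#'   `PE`, `TPI` (as produced by [forensic_summary()]); rows with `NA`
#'   values (untestable loci) are dropped and listed in the result.
#' @param combined_het `"product"` (default) or `"mean"` for Ho and He.
#' @return list with `loci_used`, `loci_dropped` and `combined`, a named
#'   numeric vector (`Ho`, `He`, `PM`, `PD`, `PE`, `TPI`).
#' @export
combine_forensic <- function(per_locus, combined_het = c("product", "mean")) {
  combined_het <- match.arg(combined_het)
  stopifnot(nrow(per_locus) >= 1L)
  ok <- stats::complete.cases(per_locus[, c("Ho", "He", "PM", "PE")])
  dropped <- per_locus$locus[!ok]
  pl <- per_locus[ok, ]
  if (!nrow(pl)) stop("no testable loci to combine", call. = FALSE)
  agg_het <- if (combined_het == "product") prod else mean
  combined <- c(
    Ho = agg_het(pl$Ho),
    He = agg_het(pl$He),
    PM = prod(pl$PM),
    PD = 1 - prod(1 - pl$PD),
    PE = 1 - prod(1 - pl$PE),
    TPI = prod(pl$TPI))
  list(loci_used = pl$locus, loci_dropped = dropped, combined = combined)
}

#' Per-locus and combined forensic parameters
#'
#' The full statistics table: for every locus in every group, the typed
#' count n, observed (Ho) and homozygous (Hom) proportions, expected
#' heterozygosity (He), polymorphism information content (PIC), probability
#' of match (PM), power of discrimination (PD), power of exclusion (PE) and
#' typical paternity index (TPI), plus one `Combined` row per group
#' (PIC is per-locus only and is `NA` in the combined row).
#'
#' @param t a [genotype_table].
#' @param grouping `"population"` or `"pooled"`.
#' @param loci locus names to include; `NULL` for all.
#' @param combined_het how to combine Ho/He across loci, see
#'   [combine_forensic()].
#' @return data frame of class `str_forensic` with columns `group`, `locus`,
#'   `n`, `Ho`, `Hom`, `He`, `PIC`, `PM`, `PD`, `PE`, `TPI`; combined rows
#'   have `locus == "Combined"`.
#' @examples
#' t <- simulate_population(population_spec("P1", 60, list(
#'   L1 = c(`8` = 0.5, `9` = 0.5),
#'   L2 = c(`10` = 0.25, `11` = 0.25, `12` = 0.5))), seed = 3)
#' forensic_summary(t)
#' @export
forensic_summary <- function(t, grouping = c("population", "pooled"),
                             loci = NULL,
                             combined_het = c("product", "mean")) {
  stopifnot(inherits(t, "genotype_table"))
  grouping <- match.arg(grouping)
  combined_het <- match.arg(combined_het)
  if (!is.null(loci)) t <- subset_genotypes(t, loci = loci)
  f <- allele_frequencies(t, grouping)
  g <- genotype_frequencies(t, grouping)
  groups <- if (grouping == "population") populations(t) else POOLED_LABEL
  rows <- list()
  for (gr in groups) {
    per <- data.frame(group = gr, locus = t$loci,
                      n = NA_integer_, Ho = NA_real_, Hom = NA_real_,
                      He = NA_real_, PIC = NA_real_, PM = NA_real_,
                      PD = NA_real_, PE = NA_real_, TPI = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(t$loci)) {
      loc <- t$loci[i]
      n <- typed_count(f, loc, gr)
      per$n[i] <- n
      if (n == 0L) next
      ho <- observed_heterozygosity(
        t, loc, if (grouping == "population") gr else NULL)
      hom <- 1 - ho
      per$Ho[i] <- ho
      per$Hom[i] <- hom
      per$He[i] <- expected_heterozygosity(f, loc, gr)
      per$PIC[i] <- pic(f, loc, gr)
      per$PM[i] <- match_probability(g, loc, gr)
      per$PD[i] <- power_of_discrimination(per$PM[i])
      per$PE[i] <- power_of_exclusion(ho, hom)
      per$TPI[i] <- suppressWarnings(typical_paternity_index(hom))
    }
    comb <- combine_forensic(per, combined_het)
    comb_row <- data.frame(group = gr, locus = "Combined",
                           n = NA_integer_,
                           Ho = comb$combined[["Ho"]],
                           Hom = NA_real_,
                           He = comb$combined[["He"]],
                           PIC = NA_real_,
                           PM = comb$combined[["PM"]],
                           PD = comb$combined[["PD"]],
                           PE = comb$combined[["PE"]],
                           TPI = comb$combined[["TPI"]],
                           stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rbind(per, comb_row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("str_forensic", "data.frame")
  out
}
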