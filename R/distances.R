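pair_loci <- function(f, group_x, group_y, loci = NULL) {
  sizes <- freq_sizes(f)
  typed_x <- sizes$locus[sizes$group == group_x & sizes$n > 0]
  typed_y <- sizes$locus[sizes$group == group_y & sizes$n > 0]
  if (!length(typed_x) && !length(typed_y))
    stop("unknown or empty groups: ", group_x, ", ", group_y, call. = FALSE)
  common <- intersect(typed_x, typed_y)
  if (!is.null(loci)) {
    dropped <- setdiff(loci, common)
    if (length(dropped))
      warning("locus untyped in one group, dropped: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    common <- intersect(loci, common)
  }
  if (!length(common))
    stop("no locus typed in both groups (", group_x, ", ", group_y, ")",
         call. = FALSE)
  common
}

#' Expected homozygosity within a group
#'
#' `J = mean over loci of sum(p_i^2)`: the chance two allele draws from the
#' same group match, averaged across loci. The building block of the
#' homozygosity-based F_st.
#'
#' @param f an `str_allele_freqs` table.
#' @param group group label.
#' @param loci locus names; `NULL` for all loci typed in the group.
#' @return expected homozygosity in \[0, 1\].
#' @export
expected_homozygosity <- function(f, group, loci = NULL) {
  stopifnot(inherits(f, "str_allele_freqs"))
  sizes <- freq_sizes(f)
  if (is.null(loci)) loci <- sizes$locus[sizes$group == group & sizes$n > 0]
  if (!length(loci)) stop("no typed locus in group ", group, call. = FALSE)
  mean(vapply(loci, function(loc) {
    p <- allele_freq_vector(f, loc, group)
    if (!length(p)) stop("locus ", loc, " untyped in group ", group,
                         call. = FALSE)
    sum(p^2)
  }, numeric(1)))
}

cross_homozygosity <- function(f, group_x, group_y, loci) {
  mean(vapply(loci, function(loc) {
    x <- allele_freq_vector(f, loc, group_x)
    y <- allele_freq_vector(f, loc, group_y)
    alle <- union(names(x), names(y))
    sum(ifelse(alle %in% names(x), x[alle], 0) *
          ifelse(alle %in% names(y), y[alle], 0))
  }, numeric(1)))
}

#' Nei's D_A distance between two populations
#'
#' `D_A = 1 - (1/r) * sum_j sum_i sqrt(x_ij * y_ij)` over the union of
#' alleles at each of the `r` shared loci (alleles absent from one
#' population contribute 0). 0 for identical frequency vectors, 1 when the
#' populations share no alleles.
#'
#' @param f an `str_allele_freqs` table computed per population.
#' @param group_x,group_y population labels.
#' @param loci loci to use; `NULL` for all loci typed in both populations.
#' @return distance in \[0, 1\].
#' @export
nei_da <- function(f, group_x, group_y, loci = NULL) {
  stopifnot(inherits(f, "str_allele_freqs"))
  loci <- pair_loci(f, group_x, group_y, loci)
  bc <- vapply(loci, function(loc) {
    x <- allele_freq_vector(f, loc, group_x)
    y <- allele_freq_vector(f, loc, group_y)
    alle <- union(names(x), names(y))
    sum(sqrt(ifelse(alle %in% names(x), x[alle], 0) *
               ifelse(alle %in% names(y), y[alle], 0)))
  }, numeric(1))
  1 - mean(bc)
}

#' Homozygosity-based F_st between two populations
#'
#' `F_st = ((J_x + J_y)/2 - J_xy) / (1 - J_xy)` with `J_x`, `J_y` the
#' within-population expected homozygosities and `J_xy` the cross-population
#' homozygosity, each averaged over loci before the ratio is formed. Two
#' populations fixed for the same allele (`J_xy = 1`) have F_st 0; negative
#' sampling estimates are clipped to 0 (attribute `clipped`).
#'
#' @inheritParams nei_da
#' @return F_st in \[0, 1\] with attribute `clipped` (logical).
#' @export
fst_pair <- function(f, group_x, group_y, loci = NULL) {
  stopifnot(inherits(f, "str_allele_freqs"))
  loci <- pair_loci(f, group_x, group_y, loci)
  jx <- expected_homozygosity(f, group_x, loci)
  jy <- expected_homozygosity(f, group_y, loci)
  jxy <- cross_homozygosity(f, group_x, group_y, loci)
  if (1 - jxy < 1e-12) return(structure(0, clipped = FALSE))
  v <- ((jx + jy) / 2 - jxy) / (1 - jxy)
  structure(max(v, 0), clipped = v < 0)
}

#' Pairwise Nei D_A and F_st matrices across all populations
#'
#' @param f an `str_allele_freqs` table computed per population (>= 2
#'   populations).
#' @param loci loci to use; per pair, restricted to loci typed in both.
#' @return object of class `str_distances`: list with `populations`, `da`
#'   and `fst` (symmetric matrices, zero diagonal), `loci_used` (loci
#'   requested) and `fst_clipped` (logical matrix flagging negative
#'   estimates clipped to 0).
#' @examples
#' t <- simulate_divergent_pair(list(L1 = c(`8` = 0.5, `9` = 0.5)),
#'                              divergence = 0.5, n = 100, seed = 2)
#' distance_matrices(allele_frequencies(t))
#' @export
distance_matrices <- function(f, loci = NULL) {
  stopifnot(inherits(f, "str_allele_freqs"))
  pops <- unique(freq_sizes(f)$group)
  if (length(pops) < 2L)
    stop("distances require at least two populations", call. = FALSE)
  k <- length(pops)
  da <- matrix(0, k, k, dimnames = list(pops, pops))
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  clipped <- matrix(FALSE, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      da[i, j] <- da[j, i] <- nei_da(f, pops[i], pops[j], loci)
      fv <- fst_pair(f, pops[i], pops[j], loci)
      fst[i, j] <- fst[j, i] <- as.numeric(fv)
      clipped[i, j] <- clipped[j, i] <- attr(fv, "clipped")
    }
  }
  structure(list(populations = pops, da = da, fst = fst,
                 loci_used = if (is.null(loci)) unique(freq_sizes(f)$locus)
                 else loci,
                 fst_clipped = clipped),
            class = "str_distances")
}

#' @export
print.str_distances <- function(x, ...) {
  cat("Pairwise distances over", length(x$populations), "populations\n")
  cat("Nei D_A:\n"); print(round(x$da, 4))
  cat("F_st:\n"); print(round(x$fst, 4))
  invisible(x)
}

#' Export distance matrices as TSV
#'
#' Writes both matrices in long form (`popA`, `popB`, `DA`, `FST`), one row
#' per unordered pair.
#'
#' @param d an `str_distances` object.
#' @param file path or connection; `NULL` to only return the lines.
#' @return invisibly, the lines written.
#' @export
write_distance_table <- function(d, file = NULL) {
  stopifnot(inherits(d, "str_distances"))
  pops <- d$populations
  rows <- c("popA\tpopB\tDA\tFST")
  for (i in seq_len(length(pops) - 1)) {
    for (j in seq(i + 1, length(pops))) {
      rows <- c(rows, paste(pops[i], pops[j],
                            format(d$da[i, j], digits = 8),
                            format(d$fst[i, j], digits = 8), sep = "\t"))
    }
  }
  if (!is.null(file)) writeLines(rows, file)
  invisible(rows)
}
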