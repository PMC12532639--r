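POOLED_LABEL <- "all"

resolve_groups <- function(t, grouping = c("population", "pooled")) {
  grouping <- match.arg(grouping)
  if (grouping == "population") {
    pops <- populations(t)
    stats::setNames(lapply(pops, function(p) t$population_id == p), pops)
  } else {
    stats::setNames(list(rep(TRUE, n_samples(t))), POOLED_LABEL)
  }
}

#' Allele frequency tables per population or pooled
#'
#' For every (locus, group) pair, counts alleles over the samples typed at
#' that locus (missing calls are dropped per locus, not per sample) and
#' divides by 2n. Every frequency is therefore a rational k/(2n).
#'
#' @param t a [genotype_table].
#' @param grouping `"population"` (one group per population, in order of
#'   first appearance) or `"pooled"` (a single group labelled `"all"`).
#' @return a data frame of class `str_allele_freqs` with columns `locus`,
#'   `group`, `allele`, `count`, `frequency` (alleles in numeric order within
#'   each locus/group), and an attribute `sizes`: a data frame
#'   (`locus`, `group`, `n`) of typed-individual counts, including
#'   zero-typed combinations.
#' @examples
#' t <- simulate_population(population_spec("P1", 50,
#'   list(CSF1PO = c(`10` = 0.4, `11` = 0.6))), seed = 1)
#' allele_frequencies(t)
#' @export
allele_frequencies <- function(t, grouping = c("population", "pooled")) {
  stopifnot(inherits(t, "genotype_table"))
  groups <- resolve_groups(t, grouping)
  rows <- list(); sizes <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    for (loc in t$loci) {
      a1 <- t$a1[sel, loc]; a2 <- t$a2[sel, loc]
      typed <- !is.na(a1)
      n <- sum(typed)
      sizes[[length(sizes) + 1L]] <-
        data.frame(locus = loc, group = g, n = n, stringsAsFactors = FALSE)
      if (n == 0L) next
      tab <- table(c(a1[typed], a2[typed]))
      alle <- sort_alleles(names(tab))
      cnt <- as.integer(tab[alle])
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, group = g, allele = alle, count = cnt,
        frequency = cnt / (2 * n), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), group = character(), allele = character(),
               count = integer(), frequency = numeric())
  rownames(out) <- NULL
  attr(out, "sizes") <- do.call(rbind, sizes)
  attr(out, "grouping") <- match.arg(grouping)
  class(out) <- c("str_allele_freqs", "data.frame")
  out
}

#' Genotype frequency tables per population or pooled
#'
#' Counts unordered genotypes (the smaller allele listed first) over typed
#' individuals and divides by n.
#'
#' @inheritParams allele_frequencies
#' @return a data frame of class `str_genotype_freqs` with columns `locus`,
#'   `group`, `allele1`, `allele2`, `count`, `frequency`, plus the same
#'   `sizes` attribute as [allele_frequencies()].
#' @export
genotype_frequencies <- function(t, grouping = c("population", "pooled")) {
  stopifnot(inherits(t, "genotype_table"))
  groups <- resolve_groups(t, grouping)
  rows <- list(); sizes <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    for (loc in t$loci) {
      a1 <- t$a1[sel, loc]; a2 <- t$a2[sel, loc]
      typed <- !is.na(a1)
      n <- sum(typed)
      sizes[[length(sizes) + 1L]] <-
        data.frame(locus = loc, group = g, n = n, stringsAsFactors = FALSE)
      if (n == 0L) next
      key <- paste(a1[typed], a2[typed], sep = "/")
      tab <- table(key)
      parts <- strsplit(names(tab), "/", fixed = TRUE)
      g1 <- vapply(parts, `[`, "", 1L)
      g2 <- vapply(parts, `[`, "", 2L)
      ord <- order(allele_numeric(g1), allele_numeric(g2))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, group = g, allele1 = g1[ord], allele2 = g2[ord],
        count = as.integer(tab)[ord],
        frequency = as.integer(tab)[ord] / n, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), group = character(),
               allele1 = character(), allele2 = character(),
               count = integer(), frequency = numeric())
  rownames(out) <- NULL
  attr(out, "sizes") <- do.call(rbind, sizes)
  attr(out, "grouping") <- match.arg(grouping)
  class(out) <- c("str_genotype_freqs", "data.frame")
  out
}

freq_sizes <- function(f) attr(f, "sizes")

#' Typed-individual count for one locus and group
#'
#' @param f an `str_allele_freqs` or `str_genotype_freqs` table.
#' @param locus,group names identifying the cell.
#' @return number of individuals typed at that locus in that group.
#' @export
typed_count <- function(f, locus, group) {
  s <- freq_sizes(f)
  i <- which(s$locus == locus & s$group == group)
  if (!length(i)) stop("no such locus/group: ", locus, "/", group,
                       call. = FALSE)
  s$n[i]
}

#' Allele frequency vector for one locus and group
#'
#' @inheritParams typed_count
#' @param f an `str_allele_freqs` table.
#' @return named numeric vector of frequencies (names = allele labels,
#'   numeric order); length 0 when the locus is untyped in that group.
#' @export
allele_freq_vector <- function(f, locus, group) {
  stopifnot(inherits(f, "str_allele_freqs"))
  sub <- f[f$locus == locus & f$group == group, ]
  stats::setNames(sub$frequency, sub$allele)
}

#' Population-by-allele frequency matrix for one locus
#'
#' The numeric matrix behind the allele-frequency heatmap: one row per
#' population, one column per allele observed at the locus in any
#' population (numeric order); alleles absent from a population get 0, so
#' each row sums to 1.
#'
#' @param f an `str_allele_freqs` table computed with
#'   `grouping = "population"`.
#' @param locus locus name.
#' @return numeric matrix, rownames = populations, colnames = alleles.
#' @export
heatmap_matrix <- function(f, locus) {
  stopifnot(inherits(f, "str_allele_freqs"))
  if (identical(attr(f, "grouping"), "pooled"))
    stop("heatmap_matrix needs per-population frequencies", call. = FALSE)
  if (!locus %in% freq_sizes(f)$locus)
    stop("unknown locus: ", locus, "; valid loci: ",
         paste(unique(freq_sizes(f)$locus), collapse = ", "), call. = FALSE)
  sub <- f[f$locus == locus, ]
  pops <- unique(freq_sizes(f)$group)
  alle <- sort_alleles(unique(sub$allele))
  m <- matrix(0, length(pops), length(alle),
              dimnames = list(pops, alle))
  if (nrow(sub)) m[cbind(sub$group, sub$allele)] <- sub$frequency
  m
}

#' Export a frequency table as TSV
#'
#' Writes the standard forensic layout: rows = alleles (or genotypes),
#' columns = locus within group, plus an `N` row of typed-individual counts.
#'
#' @param f an `str_allele_freqs` or `str_genotype_freqs` table.
#' @param file path or connection; `NULL` to only return the lines.
#' @return invisibly, the lines written.
#' @export
write_freq_table <- function(f, file = NULL) {
  sizes <- freq_sizes(f)
  cols <- paste(sizes$locus, sizes$group, sep = "|")
  if (inherits(f, "str_genotype_freqs")) {
    keys <- unique(paste(f$allele1, f$allele2, sep = "/"))
    keyvals <- strsplit(keys, "/", fixed = TRUE)
    ord <- order(as.numeric(vapply(keyvals, `[`, "", 1L)),
                 as.numeric(vapply(keyvals, `[`, "", 2L)))
    keys <- keys[ord]
    rowkey <- paste(f$allele1, f$allele2, sep = "/")
  } else {
    keys <- sort_alleles(unique(f$allele))
    rowkey <- f$allele
  }
  m <- matrix("", length(keys) + 1L, length(cols),
              dimnames = list(c(keys, "N"), cols))
  fcol <- paste(f$locus, f$group, sep = "|")
  m[cbind(rowkey, fcol)] <- format(f$frequency, digits = 8, trim = TRUE)
  m["N", ] <- as.character(sizes$n)
  lines <- c(paste(c("key", cols), collapse = "\t"),
             unname(vapply(rownames(m), function(r)
               paste(c(r, m[r, ]), collapse = "\t"), character(1))))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
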