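#' @useDynLib strpopgen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Missing-data markers accepted on input; "0" is written on output.
MISSING_MARKERS <- c("0", "", "NA")

#' Canonicalize STR allele labels
#'
#' Allele labels are repeat counts, possibly fractional ("point alleles" such
#' as `"9.3"` for a partial repeat). Labels are stored as canonical strings and
#' compared numerically, which avoids floating-point equality problems:
#' `"12.0"` becomes `"12"`, `"9.30"` becomes `"9.3"`, leading zeros are
#' dropped.
#'
#' @param x character vector of allele labels.
#' @return character vector of canonical labels; non-numeric input is an error.
#' @examples
#' canonicalize_allele(c("12.0", "9.3", "07"))
#' @export
canonicalize_allele <- function(x) {
  x <- trimws(as.character(x))
  bad <- !grepl("^[0-9]+(\\.[0-9]+)?$", x) & !is.na(x)
  if (any(bad)) {
    stop("non-numeric allele label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  has_dot <- !is.na(x) & grepl("\\.", x)
  x[has_dot] <- sub("\\.$", "", sub("\\.?0*$", "", x[has_dot]))
  x <- sub("^0+([0-9])", "\\1", x)
  x
}

#' Numeric value of allele labels
#'
#' @param x character vector of allele labels.
#' @return numeric vector (repeat counts).
#' @export
allele_numeric <- function(x) as.numeric(x)

#' Sort allele labels in numeric order
#'
#' @param x character vector of allele labels.
#' @return `x` sorted by repeat count (9.3 sorts before 10).
#' @export
sort_alleles <- function(x) x[order(allele_numeric(x))]

new_genotype_table <- function(sample_id, population_id, loci, a1, a2) {
  stopifnot(is.character(sample_id), is.character(population_id),
            is.character(loci), is.matrix(a1), is.matrix(a2),
            nrow(a1) == length(sample_id), ncol(a1) == length(loci),
            identical(dim(a1), dim(a2)))
  colnames(a1) <- colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- NULL
  structure(
    list(sample_id = sample_id, population_id = population_id,
         loci = loci, a1 = a1, a2 = a2),
    class = "genotype_table")
}

#' Construct a genotype table from vectors
#'
#' Low-level constructor used by the reader and the simulator. `a1`/`a2` are
#' character matrices (samples x loci) of allele labels with `NA` for missing
#' calls; calls are stored as unordered pairs with the numerically smaller
#' allele first. A call with only one allele present is treated as fully
#' missing (diploid statistics need both alleles) with a warning.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param population_id character vector of population labels, same length.
#' @param loci character vector of locus names.
#' @param a1,a2 character matrices of allele labels (`NA` = missing).
#' @return an object of class `genotype_table` with fields `sample_id`,
#'   `population_id`, `loci`, `a1`, `a2`.
#' @export
genotype_table <- function(sample_id, population_id, loci, a1, a2) {
  sample_id <- as.character(sample_id)
  population_id <- as.character(population_id)
  loci <- as.character(loci)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(loci))
    stop("duplicate locus name: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "), call. = FALSE)
  if (length(loci) == 0L) stop("locus set is empty", call. = FALSE)
  a1 <- matrix(canonicalize_allele(a1), nrow = length(sample_id))
  a2 <- matrix(canonicalize_allele(a2), nrow = length(sample_id))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing call(s) treated as missing",
            call. = FALSE)
    a1[half] <- NA_character_
    a2[half] <- NA_character_
  }
  swap <- !is.na(a1) & allele_numeric(a1) > allele_numeric(a2)
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  new_genotype_table(sample_id, population_id, loci, a1, a2)
}

normalize_locus_headers <- function(hdr) {
  # allele columns come in pairs; accept "L L" or "L_1 L_2" dialects
  if (length(hdr) %% 2L != 0L)
    stop("odd allele column count: ", length(hdr),
         " allele columns (last header: ", hdr[length(hdr)],
         "); each locus needs exactly two columns", call. = FALSE)
  odd <- hdr[seq(1L, length(hdr), by = 2L)]
  even <- hdr[seq(2L, length(hdr), by = 2L)]
  base1 <- sub("_[12]$", "", odd)
  base2 <- sub("_[12]$", "", even)
  mism <- base1 != base2
  if (any(mism))
    stop("allele column pair does not name one locus: '",
         odd[which(mism)[1]], "' / '", even[which(mism)[1]], "'",
         call. = FALSE)
  base1
}

#' Read a tab-delimited STR genotype table
#'
#' Expects the common forensic layout: a header row, column 1 = sample ID,
#' column 2 = population ID, then two columns per locus carrying the two
#' allele calls of each diploid genotype. Point alleles ("9.3") are kept
#' exactly. The two columns of a locus may share one header (`CSF1PO CSF1PO`)
#' or carry `_1`/`_2` suffixes (`CSF1PO_1 CSF1PO_2`); both dialects parse to
#' the same table. `"0"`, the empty string and `"NA"` mark missing calls.
#'
#' @param file path or connection to tab-delimited text.
#' @param missing_markers tokens interpreted as missing allele calls.
#' @return a [genotype_table].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("ind\tpop\tCSF1PO\tCSF1PO", "S1\tP1\t12\t9.3"), f)
#' read_genotype_table(f)
#' @export
read_genotype_table <- function(file, missing_markers = MISSING_MARKERS) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = NULL,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("need at least 3 columns (sample ID, population ID, alleles); got ",
         ncol(df), call. = FALSE)
  loci <- normalize_locus_headers(names(df)[-(1:2)])
  n <- nrow(df)
  if (n == 0L) stop("no data rows", call. = FALSE)
  L <- length(loci)
  a1 <- matrix(NA_character_, n, L)
  a2 <- matrix(NA_character_, n, L)
  for (l in seq_len(L)) {
    for (slot in 1:2) {
      col_idx <- 2L + 2L * (l - 1L) + slot
      tok <- trimws(df[[col_idx]])
      tok[tok %in% missing_markers] <- NA_character_
      bad <- !is.na(tok) & !grepl("^[0-9]+(\\.[0-9]+)?$", tok)
      if (any(bad)) {
        i <- which(bad)[1]
        stop("non-numeric allele '", tok[i], "' at row ", i,
             ", column ", col_idx, " (locus ", loci[l], ")", call. = FALSE)
      }
      if (slot == 1L) a1[, l] <- tok else a2[, l] <- tok
    }
  }
  genotype_table(df[[1]], df[[2]], loci, a1, a2)
}

#' Populations of a genotype table
#'
#' @param t a [genotype_table].
#' @return population labels in order of first appearance.
#' @export
populations <- function(t) unique(t$population_id)

#' Number of samples in a genotype table
#'
#' @param t a [genotype_table].
#' @return integer sample count.
#' @export
n_samples <- function(t) length(t$sample_id)

#' Subset a genotype table by loci and/or populations
#'
#' @param t a [genotype_table].
#' @param loci locus names to keep, or `NULL` for all (original order kept).
#' @param populations population labels to keep, or `NULL` for all.
#' @return a [genotype_table] restricted to the selection; sample and locus
#'   ordering is preserved.
#' @export
subset_genotypes <- function(t, loci = NULL, populations = NULL) {
  stopifnot(inherits(t, "genotype_table"))
  keep_loci <- t$loci
  if (!is.null(loci)) {
    unknown <- setdiff(loci, t$loci)
    if (length(unknown))
      stop("unknown locus: ", paste(unknown, collapse = ", "),
           "; valid loci: ", paste(t$loci, collapse = ", "), call. = FALSE)
    keep_loci <- t$loci[t$loci %in% loci]
  }
  keep_rows <- rep(TRUE, n_samples(t))
  if (!is.null(populations)) {
    pops <- unique(t$population_id)
    unknown <- setdiff(populations, pops)
    if (length(unknown))
      stop("unknown population: ", paste(unknown, collapse = ", "),
           "; valid populations: ", paste(pops, collapse = ", "),
           call. = FALSE)
    keep_rows <- t$population_id %in% populations
  }
  new_genotype_table(t$sample_id[keep_rows], t$population_id[keep_rows],
                     keep_loci,
                     t$a1[keep_rows, keep_loci, drop = FALSE],
                     t$a2[keep_rows, keep_loci, drop = FALSE])
}

#' Write a genotype table as tab-delimited text
#'
#' Inverse of [read_genotype_table()]: the written file reads back to an
#' identical table (canonical allele labels, duplicated locus headers,
#' missing calls written as `missing_marker`).
#'
#' @param t a [genotype_table].
#' @param file path or connection; if `NULL` nothing is written.
#' @param missing_marker token written for missing calls.
#' @return invisibly, the lines of the file as a character vector.
#' @export
write_genotype_table <- function(t, file = NULL, missing_marker = "0") {
  stopifnot(inherits(t, "genotype_table"))
  hdr <- paste(c("ind", "pop", rep(t$loci, each = 2L)), collapse = "\t")
  a1 <- t$a1; a2 <- t$a2
  a1[is.na(a1)] <- missing_marker
  a2[is.na(a2)] <- missing_marker
  body <- vapply(seq_len(n_samples(t)), function(i) {
    cells <- as.vector(rbind(a1[i, ], a2[i, ]))
    paste(c(t$sample_id[i], t$population_id[i], cells), collapse = "\t")
  }, character(1))
  lines <- c(hdr, body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Combine genotype tables row-wise
#'
#' Used by the simulator to stack populations. Tables must share the same
#' locus set (order of the first table wins).
#'
#' @param ... [genotype_table] objects.
#' @return a single [genotype_table].
#' @export
bind_genotype_tables <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], "genotype_table"))
    ts <- ts[[1]]
  stopifnot(length(ts) >= 1L, all(vapply(ts, inherits, TRUE, "genotype_table")))
  loci <- ts[[1]]$loci
  for (t in ts[-1])
    if (!setequal(t$loci, loci))
      stop("tables have different locus sets", call. = FALSE)
  new_genotype_table(
    unlist(lapply(ts, `[[`, "sample_id")),
    unlist(lapply(ts, `[[`, "population_id")),
    loci,
    do.call(rbind, lapply(ts, function(t) t$a1[, loci, drop = FALSE])),
    do.call(rbind, lapply(ts, function(t) t$a2[, loci, drop = FALSE])))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("STR genotype table: ", n_samples(x), " samples, ",
      length(x$loci), " loci, ", length(populations(x)),
      " population(s)\n", sep = "")
  cat("  loci: ", paste(utils::head(x$loci, 8), collapse = ", "),
      if (length(x$loci) > 8) ", ..." else "", "\n", sep = "")
  cat("  populations: ", paste(populations(x), collapse = ", "), "\n",
      sep = "")
  miss <- mean(is.na(x$a1))
  cat("  missing calls: ", format(100 * miss, digits = 3), "%\n", sep = "")
  invisible(x)
}
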