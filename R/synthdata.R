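#' Specification of a synthetic population
#'
#' Describes one population to simulate: its label, size, per-locus allele
#' frequency vectors, an inbreeding coefficient and a missing-call rate.
#' Inbreeding follows the mixture model: with probability `fis` an
#' individual's two alleles at a locus are identical by descent (one draw,
#' duplicated), otherwise two independent draws — giving the exact marginal
#' `Ho = (1 - fis) * He`.
#'
#' @param label population name.
#' @param n number of individuals (>= 1).
#' @param freqs named list: locus name -> named numeric vector of allele
#'   frequencies (names are allele labels, values sum to 1).
#' @param fis inbreeding coefficient in \[0, 1\].
#' @param missing_rate probability that a call is dropped, in \[0, 1).
#' @return an object of class `population_spec`.
#' @examples
#' population_spec("P1", 100, list(CSF1PO = c(`9.3` = 0.2, `10` = 0.8)))
#' @export
population_spec <- function(label, n, freqs, fis = 0, missing_rate = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (!is.list(freqs) || is.null(names(freqs)) || !all(nzchar(names(freqs))))
    stop("freqs must be a named list of per-locus frequency vectors",
         call. = FALSE)
  for (loc in names(freqs)) {
    p <- freqs[[loc]]
    if (!is.numeric(p) || is.null(names(p)) || any(p < 0))
      stop("freqs[['", loc, "']] must be a named non-negative numeric vector",
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop("freqs[['", loc, "']] must sum to 1 (got ", sum(p), ")",
           call. = FALSE)
    names(freqs[[loc]]) <- canonicalize_allele(names(p))
  }
  if (!is.numeric(fis) || fis < 0 || fis > 1)
    stop("fis must be in [0, 1]", call. = FALSE)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(label = label, n = n, freqs = freqs, fis = fis,
                 missing_rate = missing_rate),
            class = "population_spec")
}

draw_population <- function(spec) {
  n <- spec$n
  loci <- names(spec$freqs)
  a1 <- matrix(NA_character_, n, length(loci))
  a2 <- matrix(NA_character_, n, length(loci))
  for (l in seq_along(loci)) {
    p <- spec$freqs[[loci[l]]]
    alle <- names(p)
    ibd <- stats::runif(n) < spec$fis
    x <- sample(alle, n, replace = TRUE, prob = p)
    y <- sample(alle, n, replace = TRUE, prob = p)
    y[ibd] <- x[ibd]
    if (spec$missing_rate > 0) {
      drop <- stats::runif(n) < spec$missing_rate
      x[drop] <- NA_character_
      y[drop] <- NA_character_
    }
    a1[, l] <- x
    a2[, l] <- y
  }
  genotype_table(sprintf("%s_%04d", spec$label, seq_len(n)),
                 rep(spec$label, n), loci, a1, a2)
}

#' Simulate a genotype table for one population
#'
#' @param spec a [population_spec].
#' @param seed optional integer seed; when given, results are reproducible.
#' @return a [genotype_table] with `spec$n` samples.
#' @examples
#' simulate_population(population_spec("P1", 5,
#'   list(L1 = c(`8` = 0.5, `9` = 0.5))), seed = 1)
#' @export
simulate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  draw_population(spec)
}

#' Simulate a multi-population genotype table
#'
#' @param specs list of [population_spec] objects (distinct labels).
#' @param seed optional integer seed, set once before all populations.
#' @return a [genotype_table] stacking all populations.
#' @export
simulate_dataset <- function(specs, seed = NULL) {
  stopifnot(is.list(specs), length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "population_spec")))
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("population labels must be distinct", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bind_genotype_tables(lapply(specs, draw_population))
}

#' Perturb allele-frequency vectors by a multiplicative log-normal tilt
#'
#' Each frequency is multiplied by `exp(divergence * z)` with independent
#' standard-normal `z`, then renormalized. `divergence = 0` returns the
#' input unchanged (exactly); larger values push the vectors further apart
#' on average. Uses the current RNG state.
#'
#' @param freqs named list of named frequency vectors (see
#'   [population_spec()]).
#' @param divergence non-negative perturbation scale.
#' @return a frequency list of the same shape.
#' @export
perturb_freqs <- function(freqs, divergence) {
  stopifnot(is.numeric(divergence), divergence >= 0)
  if (divergence == 0) return(freqs)
  lapply(freqs, function(p) {
    w <- p * exp(divergence * stats::rnorm(length(p)))
    w / sum(w)
  })
}

#' Simulate two populations at a controlled divergence
#'
#' Population 1 is drawn from `base_freqs`; population 2 from a perturbed
#' copy (see [perturb_freqs()]). With `divergence = 0` both populations are
#' drawn from identical frequencies.
#'
#' @param base_freqs named list of named frequency vectors.
#' @param divergence non-negative perturbation scale.
#' @param n individuals per population.
#' @param seed optional integer seed.
#' @param labels the two population labels.
#' @param fis,missing_rate passed to both [population_spec()]s.
#' @return a [genotype_table] with `2 * n` samples; the generating
#'   frequencies of population 2 are attached as attribute `freqs2`.
#' @export
simulate_divergent_pair <- function(base_freqs, divergence, n, seed = NULL,
                                    labels = c("pop1", "pop2"),
                                    fis = 0, missing_rate = 0) {
  stopifnot(length(labels) == 2L, labels[1] != labels[2])
  if (!is.null(seed)) set.seed(seed)
  spec1 <- population_spec(labels[1], n, base_freqs, fis, missing_rate)
  freqs2 <- perturb_freqs(spec1$freqs, divergence)
  spec2 <- population_spec(labels[2], n, freqs2, fis, missing_rate)
  out <- bind_genotype_tables(draw_population(spec1), draw_population(spec2))
  attr(out, "freqs2") <- freqs2
  out
}
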