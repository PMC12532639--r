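# Independent oracles for the exact Hardy-Weinberg test. Both are written
# deliberately differently from the package implementation: the first
# enumerates perfect matchings of distinguishable allele copies, the second
# enumerates genotype tables with nested loops and evaluates the factorial
# formula directly.

# canonical key for a genotype configuration: sorted "a/b" pairs, one per
# individual, joined by ";"
config_key_from_pairs <- function(a, b) {
  lo <- pmin(as.numeric(a), as.numeric(b))
  hi <- pmax(as.numeric(a), as.numeric(b))
  paste(sort(paste(lo, hi, sep = "/")), collapse = ";")
}

config_key <- function(c) {
  gc <- c$genotype_counts
  a <- rep(gc$allele1, gc$count)
  b <- rep(gc$allele2, gc$count)
  config_key_from_pairs(a, b)
}

# Oracle 1: exhaustively match 2n distinguishable allele copies into n
# unordered pairs; the null probability of a configuration is the fraction
# of matchings that produce it. Feasible up to 2n = 10.
oracle_pairing_dist <- function(alleles) {
  counts <- new.env(parent = emptyenv())
  rec <- function(idx, pairs) {
    if (!length(idx)) {
      key <- paste(sort(pairs), collapse = ";")
      prev <- if (is.null(counts[[key]])) 0 else counts[[key]]
      counts[[key]] <- prev + 1
      return(invisible())
    }
    i <- idx[1]
    for (j in idx[-1]) {
      x <- as.numeric(alleles[i]); y <- as.numeric(alleles[j])
      rec(setdiff(idx, c(i, j)),
          c(pairs, paste(min(x, y), max(x, y), sep = "/")))
    }
  }
  rec(seq_along(alleles), character(0))
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], numeric(1))
  data.frame(key = keys, prob = cnt / sum(cnt), stringsAsFactors = FALSE)
}

oracle_pairing_p <- function(alleles, observed_key) {
  d <- oracle_pairing_dist(alleles)
  p_obs <- d$prob[d$key == observed_key]
  stopifnot(length(p_obs) == 1)
  sum(d$prob[d$prob <= p_obs + 1e-12])
}

# Oracle 2: enumerate all genotype tables with the given allele counts
# (k <= 3) by nested loops over heterozygote cells; homozygote counts are
# then determined. Probability from the factorial formula, evaluated via
# lfactorial.
oracle_loop_configs <- function(counts) {
  counts <- as.integer(counts)
  k <- length(counts)
  stopifnot(k >= 1, k <= 3, sum(counts) %% 2 == 0)
  labels <- as.character(seq_len(k) * 10L)  # arbitrary numeric labels
  n <- sum(counts) / 2
  lp <- function(nij, het) {
    lfactorial(n) + sum(lfactorial(counts)) - lfactorial(2 * n) +
      het * log(2) - sum(lfactorial(nij))
  }
  out <- list()
  add <- function(hom, het_cells) {
    # hom: k homozygote counts; het_cells named vector e.g. c(`1/2` = 3)
    a <- c(rep(labels, hom),
           unlist(lapply(names(het_cells), function(nm) {
             ij <- as.integer(strsplit(nm, "/")[[1]])
             rep(labels[ij[1]], het_cells[[nm]])
           })))
    b <- c(rep(labels, hom),
           unlist(lapply(names(het_cells), function(nm) {
             ij <- as.integer(strsplit(nm, "/")[[1]])
             rep(labels[ij[2]], het_cells[[nm]])
           })))
    key <- config_key_from_pairs(a, b)
    prob <- exp(lp(c(hom, unlist(het_cells)), sum(unlist(het_cells))))
    out[[length(out) + 1L]] <<- data.frame(key = key, prob = prob,
                                           stringsAsFactors = FALSE)
  }
  if (k == 1) {
    add(counts[1] / 2, stats::setNames(integer(0), character(0)))
  } else if (k == 2) {
    for (n12 in seq(counts[1] %% 2, min(counts), by = 2))
      add(c((counts[1] - n12) / 2, (counts[2] - n12) / 2),
          c(`1/2` = n12))
  } else {
    for (n12 in 0:min(counts[1], counts[2]))
      for (n13 in 0:min(counts[1] - n12, counts[3]))
        for (n23 in 0:min(counts[2] - n12, counts[3] - n13)) {
          h1 <- counts[1] - n12 - n13
          h2 <- counts[2] - n12 - n23
          h3 <- counts[3] - n13 - n23
          if (h1 %% 2 || h2 %% 2 || h3 %% 2) next
          add(c(h1, h2, h3) / 2, c(`1/2` = n12, `1/3` = n13, `2/3` = n23))
        }
  }
  do.call(rbind, out)
}

oracle_loop_p <- function(counts, observed_key) {
  d <- oracle_loop_configs(counts)
  stopifnot(abs(sum(d$prob) - 1) < 1e-9)
  p_obs <- d$prob[d$key == observed_key]
  stopifnot(length(p_obs) == 1)
  sum(d$prob[d$prob <= p_obs * (1 + 1e-9)])
}

# build a genotype table with an exact genotype composition in one or more
# populations: comp = list(P1 = list(L1 = list(c("8","8"), c("8","9"))))
table_from_composition <- function(comp) {
  loci <- unique(unlist(lapply(comp, names)))
  sample_id <- character(0); population_id <- character(0)
  a1 <- NULL; a2 <- NULL
  for (pop in names(comp)) {
    n <- length(comp[[pop]][[1]])
    m1 <- matrix(NA_character_, n, length(loci))
    m2 <- matrix(NA_character_, n, length(loci))
    for (l in seq_along(loci)) {
      calls <- lapply(comp[[pop]][[loci[l]]], as.character)
      m1[, l] <- vapply(calls, `[`, "", 1L)
      m2[, l] <- vapply(calls, `[`, "", 2L)
    }
    sample_id <- c(sample_id, sprintf("%s_%02d", pop, seq_len(n)))
    population_id <- c(population_id, rep(pop, n))
    a1 <- rbind(a1, m1); a2 <- rbind(a2, m2)
  }
  genotype_table(sample_id, population_id, loci, a1, a2)
}

# random population spec for property tests (point alleles included)
random_spec <- function(label, n = 8, n_loci = 3, missing_rate = 0.1) {
  loci <- paste0("L", seq_len(n_loci))
  freqs <- lapply(loci, function(l) {
    k <- sample(2:5, 1)
    labels <- sample(c("7", "8", "9", "9.3", "10", "11.2", "12"), k)
    p <- stats::runif(k)
    stats::setNames(p / sum(p), labels)
  })
  names(freqs) <- loci
  population_spec(label, n, freqs, missing_rate = missing_rate)
}
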