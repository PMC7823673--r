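# Independent brute-force oracles for the mixture likelihood machinery.
# These enumerate every dropout/drop-in outcome (and, for the locus-level
# oracle, every fetal genotype pair) directly, without reusing any of the
# package's closed-form code paths.

# Allele universe convention shared with the implementation: panel alleles
# at the locus plus any extra alleles seen in evidence or genotypes.
oracle_universe <- function(freqs, locus, extra) {
  unique(c(names(freqs$entries[[locus]]), extra))
}

# P(observe exactly allele set E) by enumerating the 2^4 per-copy dropout
# patterns of the two fetal genotypes and the drop-in events (none, or one
# allele of the universe).
oracle_mixture <- function(E, mother, g1, g2, d1, d2, dropin, freqs) {
  locus <- mother$locus_id
  copies <- c(g1$alleles, g2$alleles)
  dprob <- c(d1, d1, d2, d2)
  uni <- oracle_universe(freqs, locus,
                         c(E, mother$alleles, g1$alleles, g2$alleles))
  tot <- 0
  for (mask in 0:15) {
    keep <- bitwAnd(mask, 2^(0:3)) > 0
    pr <- prod(ifelse(keep, 1 - dprob, dprob))
    surv <- unique(c(mother$alleles, copies[keep]))
    if (setequal(surv, E)) tot <- tot + pr * (1 - dropin)
    for (a in uni) {
      if (setequal(union(surv, a), E))
        tot <- tot + pr * dropin * allele_freq(freqs, locus, a)
    }
  }
  tot
}

# Child genotype distribution by direct enumeration of (maternal allele,
# paternal allele) transmissions with mutation; father = character(2) or
# "POPULATION". Returns a list of genotype allele pairs with probabilities.
oracle_child_prior <- function(mother_alleles, father, universe, pvec, r) {
  n <- length(universe)
  trans <- function(parent) {
    out <- stats::setNames(numeric(n), universe)
    for (cp in parent) {
      out[cp] <- out[cp] + 0.5 * (1 - r)
      if (r > 0) {
        w <- stats::setNames(pvec, universe)
        w[cp] <- 0
        out <- out + 0.5 * r * w / sum(w)
      }
    }
    out
  }
  mat <- trans(mother_alleles)
  pat <- if (identical(father, "POPULATION")) {
    stats::setNames(pvec / sum(pvec), universe)
  } else {
    trans(father)
  }
  probs <- list()
  for (a in universe) for (b in universe) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) +
      mat[[a]] * pat[[b]]
  }
  probs
}

# Locus likelihood under a hypothesis by summing the mixture oracle over
# every fetal genotype pair weighted by the prior oracle.
oracle_locus <- function(E, mother, af, hypothesis, params, freqs) {
  locus <- mother$locus_id
  universe <- oracle_universe(freqs, locus, c(E, mother$alleles, af$alleles))
  pvec <- allele_freq(freqs, locus, universe)
  r <- params$mutation_rate
  pri <- function(father) oracle_child_prior(mother$alleles, father,
                                             universe, pvec, r)
  pair_sum <- function(p1, p2) {
    tot <- 0
    for (k1 in names(p1)) for (k2 in names(p2)) {
      w <- p1[[k1]] * p2[[k2]]
      if (w == 0) next
      a1 <- strsplit(k1, "\r", fixed = TRUE)[[1]]
      a2 <- strsplit(k2, "\r", fixed = TRUE)[[1]]
      tot <- tot + w * oracle_mixture(E, mother,
                                      genotype(locus, a1[1], a1[2]),
                                      genotype(locus, a2[1], a2[2]),
                                      params$d1, params$d2, params$dropin,
                                      freqs)
    }
    tot
  }
  p_af <- pri(af$alleles)
  p_pop <- pri("POPULATION")
  switch(hypothesis,
         H1 = pair_sum(p_af, p_af),
         H3 = pair_sum(p_pop, p_pop),
         H2 = (pair_sum(p_af, p_pop) + pair_sum(p_pop, p_af)) / 2)
}

# Random small locus instance on <= 4 alleles: frequency table, maternal and
# alleged-father genotypes, fetal genotypes, evidence set, parameters.
rand_instance <- function() {
  n <- sample(2:4, 1)
  labels <- LETTERS[1:n]
  g <- stats::rgamma(n, 1)
  ft <- frequency_table(list(L = stats::setNames(g / sum(g), labels)))
  pick <- function() genotype("L", sample(labels, 1), sample(labels, 1))
  mother <- pick()
  # evidence always contains the maternal alleles (they never drop out)
  extra <- setdiff(labels, mother$alleles)
  E <- unique(c(mother$alleles,
                if (length(extra)) sample(extra, sample(0:min(2, length(extra)), 1))))
  list(freqs = ft, mother = mother, af = pick(), g1 = pick(), g2 = pick(),
       E = E,
       params = mixture_params(d1 = stats::runif(1, 0.001, 0.9),
                               d2 = stats::runif(1, 0.001, 0.9),
                               dropin = stats::runif(1, 0, 0.1),
                               mutation_rate = sample(c(0, 1e-8, 1e-3), 1)))
}

# A tiny fixed panel used across tests.
toy_freqs <- function() {
  frequency_table(list(
    L1 = c(A = 0.4, B = 0.3, C = 0.2, D = 0.1),
    L2 = c(A = 0.5, B = 0.5)
  ))
}

# Plasma counts object shorthand.
counts_of <- function(locus, ...) {
  plasma_counts(locus, unlist(list(...)))
}
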