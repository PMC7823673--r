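#' Stochastic parameters of the cfDNA mixture model
#'
#' The plasma evidence at a locus is modelled qualitatively: the allele set
#' observed at or above the detection threshold, given the genotypes of the
#' mother and the two fetuses. Each fetal allele copy drops out independently
#' with the fetus's dropout probability (`d1`, `d2`); maternal copies never
#' drop out, the mother being the major contributor (maternal dropout is
#' fixed at 0 and not configurable). At most one drop-in allele per locus can
#' appear: no drop-in with probability `1 - dropin`, drop-in of allele a with
#' probability `dropin * p_a` where p_a is the population frequency (with the
#' unseen-allele floor). Mutation acts on parent-to-child transmission inside
#' [child_genotype_prior()], not on the evidence.
#'
#' @param d1,d2 Dropout probabilities of fetus 1 and fetus 2 (a floor of
#'   0.001 is conventional for the minor contributors). Default 0.1.
#' @param dropin Drop-in probability c per locus. Default 0.01.
#' @param mutation_rate Per-transmission mutation probability r. Default 1e-8.
#' @param theta Theta (Fst) correction for random-man allele probabilities,
#'   Balding-Nichols form. Default 0 (Hardy-Weinberg).
#' @param silent Silent-allele probability; only 0 is supported.
#' @return An object of class `mh_params`.
#' @export
mixture_params <- function(d1 = 0.1, d2 = 0.1, dropin = 0.01,
                           mutation_rate = 1e-8, theta = 0, silent = 0) {
  vals <- c(d1 = d1, d2 = d2, dropin = dropin, mutation_rate = mutation_rate,
            theta = theta, silent = silent)
  if (any(vals < 0) || any(vals >= 1))
    stop("all mixture parameters must lie in [0, 1)")
  if (silent > 0)
    stop("silent alleles (s > 0) are not implemented; set silent = 0")
  structure(as.list(vals), class = "mh_params")
}

#' Default dropout-probability grid
#'
#' Equal dropout for both fetuses over
#' {0.001, 0.01, 0.05, 0.1, 0.2, ..., 0.9}. With `cross = TRUE`, the full
#' unequal-d cross grid over the same values.
#'
#' @param d Dropout values to use.
#' @param cross Cross d1 with d2 instead of assuming them equal.
#' @return Data frame with columns `d1`, `d2`.
#' @export
default_dropout_grid <- function(d = c(0.001, 0.01, 0.05, seq(0.1, 0.9, by = 0.1)),
                                 cross = FALSE) {
  if (cross) expand.grid(d1 = d, d2 = d) else data.frame(d1 = d, d2 = d)
}

#' Genotype distribution of a child given its parents
#'
#' Mendelian transmission with mutation: each parent passes one of its two
#' alleles with probability (1 - r)/2 each, or mutates with probability r to
#' an allele drawn from population frequencies (the transmitted allele
#' excluded, remainder renormalized). A `"POPULATION"` father stands for a
#' random man: the paternal allele is drawn from the locus's allele
#' frequencies (unseen floor applied; with `theta > 0`, Balding-Nichols
#' adjusted conditional on the maternal alleles).
#'
#' @param mother The mother's `mh_genotype`.
#' @param father The father's `mh_genotype`, or the string `"POPULATION"`.
#' @param freqs An `mh_freqs` table.
#' @param params An `mh_params` object (uses `mutation_rate` and `theta`).
#' @return Data frame with columns `allele1`, `allele2`, `prob` (unordered
#'   genotypes, zero-probability rows dropped, probabilities summing to 1).
#' @export
child_genotype_prior <- function(mother, father, freqs,
                                 params = mixture_params()) {
  stopifnot(inherits(mother, "mh_genotype"))
  locus <- mother$locus_id
  pop_father <- identical(father, "POPULATION")
  if (!pop_father) {
    stopifnot(inherits(father, "mh_genotype"))
    if (!identical(father$locus_id, locus))
      stop("mother and father genotypes are at different loci")
  }
  universe <- locus_universe(freqs, locus,
                             c(mother$alleles,
                               if (!pop_father) father$alleles))
  pvec <- allele_freq(freqs, locus, universe)
  mdist <- transmission_dist(mother$alleles, universe, pvec,
                             params$mutation_rate)
  fdist <- if (pop_father) {
    population_dist(universe, pvec, params$theta, mother$alleles)
  } else {
    transmission_dist(father$alleles, universe, pvec, params$mutation_rate)
  }
  gi <- genotype_index(length(universe))
  w <- pair_weights(mdist, fdist, gi$ia, gi$ja)
  keep <- w > 0
  out <- data.frame(allele1 = universe[gi$ia][keep],
                    allele2 = universe[gi$ja][keep],
                    prob = w[keep], stringsAsFactors = FALSE)
  out[order(out$allele1, out$allele2), , drop = FALSE]
}

#' Likelihood of a plasma allele set given all three genotypes
#'
#' Probability of observing exactly the evidence allele set in maternal
#' plasma given the maternal genotype and the genotypes of both fetuses,
#' under the dropout/drop-in model of [mixture_params()].
#'
#' @param evidence Character vector: the alleles observed at or above the
#'   detection threshold (maternal alleles included).
#' @param mother,g1,g2 `mh_genotype` objects at the same locus (mother,
#'   fetus 1, fetus 2).
#' @param params An `mh_params` object.
#' @param freqs An `mh_freqs` table (drop-in allele probabilities).
#' @return A probability in `[0, 1]`.
#' @export
mixture_likelihood <- function(evidence, mother, g1, g2, params, freqs) {
  stopifnot(inherits(mother, "mh_genotype"), inherits(g1, "mh_genotype"),
            inherits(g2, "mh_genotype"))
  locus <- mother$locus_id
  if (!identical(g1$locus_id, locus) || !identical(g2$locus_id, locus))
    stop("genotypes span different loci")
  evidence <- unique(as.character(evidence))
  universe <- unique(c(evidence, mother$alleles, g1$alleles, g2$alleles))
  cnt1 <- count_copies(g1$alleles, universe)
  cnt2 <- count_copies(g2$alleles, universe)
  q <- params$d1^cnt1 * params$d2^cnt2
  q[universe %in% mother$alleles] <- 0
  obs <- universe %in% evidence
  pdrop <- allele_freq(freqs, locus, universe)
  cc <- params$dropin
  prod_not <- prod(q[!obs])
  term_none <- (1 - cc) * prod(1 - q[obs]) * prod_not
  obs_idx <- which(obs)
  term_dropin <- 0
  for (k in seq_along(obs_idx)) {
    rest <- obs_idx[-k]
    term_dropin <- term_dropin +
      pdrop[obs_idx[k]] * prod(1 - q[rest])
  }
  term_none + cc * term_dropin * prod_not
}

#' Locus likelihood under a paternity hypothesis
#'
#' Marginalizes [mixture_likelihood()] over the genotypes of both fetuses,
#' weighting by [child_genotype_prior()] with the father dictated by the
#' hypothesis: H1 - the alleged father (AF) fathered both twins; H2 - AF
#' fathered one twin and a random man the other (heteropaternal
#' superfecundation), the two labelings averaged with equal prior; H3 -
#' random men fathered both.
#'
#' @param evidence Character vector of observed alleles.
#' @param mother,af `mh_genotype` objects for mother and alleged father.
#' @param hypothesis `"H1"`, `"H2"` or `"H3"`.
#' @param params An `mh_params` object.
#' @param freqs An `mh_freqs` table.
#' @return A probability.
#' @export
locus_likelihood <- function(evidence, mother, af,
                             hypothesis = c("H1", "H2", "H3"),
                             params, freqs) {
  hypothesis <- match.arg(hypothesis)
  eng <- locus_engine(evidence, mother, af, freqs, params)
  L <- engine_likelihoods(eng, params$d1, params$d2, params$dropin)
  L[[hypothesis]]
}

#' Likelihood ratios across loci and a dropout grid
#'
#' For every grid point (d1, d2) and every usable locus, computes the
#' likelihoods under H1, H2, H3 and the three log10 likelihood ratios
#' LR(H1,H3), LR(H2,H3), LR(H1,H2). Cumulative log10 LRs are the sums over
#' loci (the loci being treated as independent, the cumulative LR is the
#' product of per-locus LRs). Loci lacking a maternal or alleged-father
#' genotype are skipped with a warning.
#'
#' @param evidence_case Named list (locus id -> character vector of observed
#'   alleles), or an `mh_case_calls` object (converted with
#'   [evidence_from_calls()]).
#' @param mother,af `mh_profile` objects for mother and alleged father.
#' @param freqs An `mh_freqs` table.
#' @param grid Data frame with columns `d1`, `d2` (see
#'   [default_dropout_grid()]), or a numeric vector of equal-d values.
#' @param params An `mh_params` object (`d1`/`d2` are taken from the grid).
#' @param case_id Label for the result.
#' @return An object of class `mh_lr`: `case_id`, `grid`,
#'   `per_locus_log10` (array loci x contrasts x grid points) and
#'   `cumulative_log10` (matrix grid points x contrasts, columns
#'   `lr_h1_h3`, `lr_h2_h3`, `lr_h1_h2`).
#' @export
compute_lr <- function(evidence_case, mother, af, freqs,
                       grid = default_dropout_grid(),
                       params = mixture_params(),
                       case_id = NULL) {
  if (inherits(evidence_case, "mh_case_calls")) {
    if (is.null(case_id)) case_id <- evidence_case$case_id
    evidence_case <- evidence_from_calls(evidence_case)
  }
  if (is.null(case_id)) case_id <- "case"
  if (is.numeric(grid)) grid <- data.frame(d1 = grid, d2 = grid)
  stopifnot(is.data.frame(grid), all(c("d1", "d2") %in% names(grid)))
  stopifnot(inherits(mother, "mh_profile"), inherits(af, "mh_profile"))
  loci <- names(evidence_case)
  usable <- loci[loci %in% names(mother$genotypes) &
                 loci %in% names(af$genotypes)]
  if (length(usable) < length(loci))
    warning("skipping ", length(loci) - length(usable),
            " locus/loci without maternal or alleged-father genotype")
  usable <- usable[vapply(evidence_case[usable], length, integer(1)) > 0L]
  if (length(usable) == 0L)
    stop("no usable locus for LR computation")
  engines <- lapply(usable, function(loc) {
    locus_engine(evidence_case[[loc]], mother$genotypes[[loc]],
                 af$genotypes[[loc]], freqs, params)
  })
  contrasts <- c("lr_h1_h3", "lr_h2_h3", "lr_h1_h2")
  per <- array(NA_real_,
               dim = c(length(usable), 3L, nrow(grid)),
               dimnames = list(usable, contrasts, NULL))
  for (g in seq_len(nrow(grid))) {
    for (i in seq_along(engines)) {
      L <- engine_likelihoods(engines[[i]], grid$d1[g], grid$d2[g],
                              params$dropin)
      per[i, , g] <- c(log10(L$H1) - log10(L$H3),
                       log10(L$H2) - log10(L$H3),
                       log10(L$H1) - log10(L$H2))
    }
  }
  cum <- t(apply(per, c(2, 3), sum))
  colnames(cum) <- contrasts
  structure(list(case_id = case_id, grid = grid,
                 per_locus_log10 = per, cumulative_log10 = cum),
            class = "mh_lr")
}

#' @export
print.mh_lr <- function(x, ...) {
  cat("LR result for case", x$case_id, "over", nrow(x$grid), "grid points,",
      dim(x$per_locus_log10)[1], "loci\n")
  cat("cumulative log10 LR(H1,H3) range:",
      paste(format_fixed(range(x$cumulative_log10[, "lr_h1_h3"]), 3),
            collapse = " to "), "\n")
  invisible(x)
}

#' Extract the plasma evidence allele sets from locus calls
#'
#' The evidence at a locus is every allele (maternal included) at or above
#' the detection threshold. Loci failing QC or classified as UNCLASSIFIED
#' (more than two nonmaternal alleles, suspected drop-in) are excluded.
#'
#' @param calls An `mh_case_calls` object.
#' @return Named list: locus id -> character vector of alleles.
#' @export
evidence_from_calls <- function(calls) {
  stopifnot(inherits(calls, "mh_case_calls"))
  ok <- Filter(function(x) x$qc_pass && x$pattern_type != "UNCLASSIFIED" &&
                 length(x$observed_alleles) > 0L, calls$calls)
  lapply(ok, `[[`, "observed_alleles")
}

#' Screen a panel of candidate fathers
#'
#' Computes cumulative log10 LRs for each candidate as alleged father and
#' flags candidates whose LR(H2,H3) exceeds 1 anywhere on the dropout grid
#' (possible false inclusions at unrealistically high assumed dropout).
#'
#' @param evidence_case Named list of evidence allele sets (or
#'   `mh_case_calls`).
#' @param mother The mother's `mh_profile`.
#' @param candidates List of `mh_profile` objects to test as alleged father.
#' @param freqs An `mh_freqs` table.
#' @param grid Dropout grid (see [compute_lr()]).
#' @param params An `mh_params` object.
#' @return Data frame, one row per candidate: `candidate`, min/max cumulative
#'   log10 LR for each contrast, `flag_h2_h3` (TRUE when LR(H2,H3) crosses 1
#'   on the grid).
#' @export
specificity_screen <- function(evidence_case, mother, candidates, freqs,
                               grid = default_dropout_grid(),
                               params = mixture_params()) {
  if (length(candidates) == 0L) stop("empty candidate list")
  rows <- lapply(candidates, function(cand) {
    res <- compute_lr(evidence_case, mother, cand, freqs, grid, params,
                      case_id = cand$sample_id)
    cum <- res$cumulative_log10
    data.frame(candidate = cand$sample_id,
               min_log10_lr_h1_h3 = min(cum[, "lr_h1_h3"]),
               max_log10_lr_h1_h3 = max(cum[, "lr_h1_h3"]),
               min_log10_lr_h2_h3 = min(cum[, "lr_h2_h3"]),
               max_log10_lr_h2_h3 = max(cum[, "lr_h2_h3"]),
               flag_h2_h3 = any(cum[, "lr_h2_h3"] > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- internal machinery ----------------------------------------------------

# Allele universe at a locus: panel alleles plus any extra alleles seen in
# genotypes or evidence (these get the unseen-allele floor frequency).
locus_universe <- function(freqs, locus, extra = character(0)) {
  unique(c(names(freqs$entries[[locus]]), extra))
}

count_copies <- function(alleles, universe) {
  vapply(universe, function(a) sum(alleles == a), numeric(1), USE.NAMES = FALSE)
}

# P(transmitted allele) over the universe for a parent with known genotype.
transmission_dist <- function(parent, universe, pvec, r) {
  out <- numeric(length(universe))
  for (cp in parent) {
    i <- match(cp, universe)
    if (is.na(i)) stop("parental allele ", cp, " missing from allele universe")
    out[i] <- out[i] + 0.5 * (1 - r)
    if (r > 0) {
      w <- pvec
      w[i] <- 0
      out <- out + 0.5 * r * w / sum(w)
    }
  }
  out
}

# Random-man allele distribution; Balding-Nichols adjustment conditional on
# the maternal alleles when theta > 0, plain (normalized) frequencies at
# theta = 0.
population_dist <- function(universe, pvec, theta, cond_alleles) {
  if (theta > 0) {
    n_cond <- length(cond_alleles)
    na <- count_copies(cond_alleles, universe)
    p <- (na * theta + (1 - theta) * pvec) / (1 + (n_cond - 1) * theta)
  } else {
    p <- pvec
  }
  p / sum(p)
}

# Unordered genotype enumeration over n alleles: index pairs ia <= ja.
genotype_index <- function(n) {
  ia <- integer(0); ja <- integer(0)
  for (i in seq_len(n)) {
    ia <- c(ia, rep(i, n - i + 1L))
    ja <- c(ja, i:n)
  }
  list(ia = ia, ja = ja)
}

# Prior over unordered genotypes from maternal and paternal allele dists.
pair_weights <- function(mdist, fdist, ia, ja) {
  w <- mdist[ia] * fdist[ja] + ifelse(ia != ja, mdist[ja] * fdist[ia], 0)
  w / sum(w)
}

# Per-locus precomputation shared by all grid points and hypotheses.
locus_engine <- function(evidence, mother, af, freqs, params) {
  stopifnot(inherits(mother, "mh_genotype"), inherits(af, "mh_genotype"))
  locus <- mother$locus_id
  if (!identical(af$locus_id, locus))
    stop("mother and alleged-father genotypes are at different loci")
  evidence <- unique(as.character(evidence))
  universe <- locus_universe(freqs, locus,
                             c(evidence, mother$alleles, af$alleles))
  n <- length(universe)
  pvec <- allele_freq(freqs, locus, universe)
  gi <- genotype_index(n)
  m <- length(gi$ia)
  cnt <- matrix(0, m, n)
  for (k in seq_len(m)) {
    cnt[k, gi$ia[k]] <- cnt[k, gi$ia[k]] + 1
    cnt[k, gi$ja[k]] <- cnt[k, gi$ja[k]] + 1
  }
  mdist <- transmission_dist(mother$alleles, universe, pvec,
                             params$mutation_rate)
  afdist <- transmission_dist(af$alleles, universe, pvec,
                              params$mutation_rate)
  popdist <- population_dist(universe, pvec, params$theta, mother$alleles)
  list(universe = universe,
       obs = universe %in% evidence,
       mat = universe %in% mother$alleles,
       cnt = cnt,
       pdrop = pvec,
       w_af = pair_weights(mdist, afdist, gi$ia, gi$ja),
       w_pop = pair_weights(mdist, popdist, gi$ia, gi$ja))
}

# Likelihoods under H1/H2/H3 at one (d1, d2) point. The mixture-likelihood
# matrix over genotype pairs is shared by the three hypotheses; only the
# prior weight vectors differ.
engine_likelihoods <- function(eng, d1, d2, dropin) {
  L <- mixture_matrix(eng$obs, eng$mat, eng$cnt, d1, d2, dropin, eng$pdrop)
  a <- as.numeric(eng$w_af %*% L)   # row weights = fetus 1 (dropout d1)
  p <- as.numeric(eng$w_pop %*% L)
  H1 <- sum(a * eng$w_af)
  H3 <- sum(p * eng$w_pop)
  H2 <- (sum(a * eng$w_pop) + sum(p * eng$w_af)) / 2
  list(H1 = H1, H2 = H2, H3 = H3)
}

# m x m matrix of P(evidence | g1 = row, g2 = col) under the dropout/drop-in
# model; rows drop out with d1, columns with d2.
mixture_matrix <- function(obs, mat, cnt, d1, d2, dropin, pdrop) {
  m <- nrow(cnt)
  D1 <- d1^cnt
  D2 <- d2^cnt
  obs_idx <- which(obs)
  not_idx <- which(!obs)
  L <- matrix(0, m, m)
  for (i in seq_len(m)) {
    Q <- D2 * rep(D1[i, ], each = m)  # Q[j, a] = d1^cnt[i,a] * d2^cnt[j,a]
    if (any(mat)) Q[, mat] <- 0
    one_minus <- 1 - Q
    prod_not <- rowprods(Q[, not_idx, drop = FALSE])
    base <- (1 - dropin) * rowprods(one_minus[, obs_idx, drop = FALSE])
    di <- 0
    for (k in seq_along(obs_idx)) {
      di <- di + pdrop[obs_idx[k]] *
        rowprods(one_minus[, obs_idx[-k], drop = FALSE])
    }
    L[i, ] <- (base + dropin * di) * prod_not
  }
  L
}

rowprods <- function(M) {
  if (ncol(M) == 0L) return(rep(1, nrow(M)))
  out <- M[, 1]
  for (k in seq_len(ncol(M))[-1]) out <- out * M[, k]
  out
}
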