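test_that("mixture parameters validate their domain", {
  expect_error(mixture_params(d1 = 1), "\\[0, 1\\)")
  expect_error(mixture_params(silent = 0.1), "not implemented")
  p <- mixture_params()
  expect_equal(p$dropin, 0.01)
  expect_equal(p$mutation_rate, 1e-8)
  expect_equal(p$theta, 0)
})

test_that("child genotype priors are Mendelian and normalized", {
  ft <- toy_freqs()
  p0 <- mixture_params(mutation_rate = 0)
  pr <- child_genotype_prior(genotype("L1", "A", "B"),
                             genotype("L1", "C", "C"), ft, p0)
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$prob[pr$allele1 == "A" & pr$allele2 == "C"], 0.5)
  expect_equal(pr$prob[pr$allele1 == "B" & pr$allele2 == "C"], 0.5)
  # random-man father draws the paternal allele from population frequencies
  ft2 <- frequency_table(list(L1 = c(A = 0.4, B = 0.6)))
  pr2 <- child_genotype_prior(genotype("L1", "A", "A"), "POPULATION", ft2, p0)
  expect_equal(pr2$prob[pr2$allele1 == "A" & pr2$allele2 == "A"], 0.4)
  expect_equal(pr2$prob[pr2$allele1 == "A" & pr2$allele2 == "B"], 0.6)
  # normalization across random instances, with and without mutation
  withr::local_seed(17)
  for (i in 1:20) {
    inst <- rand_instance()
    for (father in list(inst$af, "POPULATION")) {
      pr <- child_genotype_prior(inst$mother, father, inst$freqs, inst$params)
      expect_equal(sum(pr$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("priors match the enumeration oracle including mutation", {
  withr::local_seed(19)
  for (i in 1:25) {
    inst <- rand_instance()
    universe <- oracle_universe(inst$freqs, "L",
                                c(inst$mother$alleles, inst$af$alleles))
    pvec <- allele_freq(inst$freqs, "L", universe)
    for (father in list(inst$af$alleles, "POPULATION")) {
      orc <- oracle_child_prior(inst$mother$alleles, father, universe, pvec,
                                inst$params$mutation_rate)
      fa <- if (identical(father, "POPULATION")) "POPULATION"
            else genotype("L", father[1], father[2])
      pr <- child_genotype_prior(inst$mother, fa, inst$freqs, inst$params)
      for (k in seq_len(nrow(pr))) {
        key <- paste(c(pr$allele1[k], pr$allele2[k]), collapse = "\r")
        expect_equal(pr$prob[k], orc[[key]], tolerance = 1e-12)
      }
    }
  }
})

test_that("mixture likelihood reproduces the forced worked cases", {
  ft <- toy_freqs()
  m <- genotype("L1", "A", "B")
  # maternal copies guarantee the evidence; nothing to explain
  expect_equal(mixture_likelihood(c("A", "B"), m, genotype("L1", "A", "B"),
                                  genotype("L1", "A", "B"),
                                  mixture_params(d1 = 0.3, d2 = 0.7,
                                                 dropin = 0), ft), 1)
  # the single fetal C copy must drop out: probability d1
  expect_equal(mixture_likelihood(c("A", "B"), m, genotype("L1", "A", "C"),
                                  genotype("L1", "A", "B"),
                                  mixture_params(d1 = 0.13, d2 = 0.5,
                                                 dropin = 0), ft), 0.13)
  # C unexplained by any contributor: drop-in only, c * p_C
  expect_equal(mixture_likelihood(c("A", "B", "C"), m,
                                  genotype("L1", "A", "A"),
                                  genotype("L1", "A", "B"),
                                  mixture_params(d1 = 0.2, d2 = 0.3,
                                                 dropin = 0.01), ft),
               0.01 * 0.2)
  # missing maternal allele is impossible evidence
  expect_equal(mixture_likelihood("A", m, genotype("L1", "A", "A"),
                                  genotype("L1", "A", "A"),
                                  mixture_params(), ft), 0)
})

test_that("mixture likelihood equals the exhaustive-outcome oracle", {
  withr::local_seed(23)
  for (i in 1:120) {
    inst <- rand_instance()
    v <- mixture_likelihood(inst$E, inst$mother, inst$g1, inst$g2,
                            inst$params, inst$freqs)
    o <- oracle_mixture(inst$E, inst$mother, inst$g1, inst$g2,
                        inst$params$d1, inst$params$d2, inst$params$dropin,
                        inst$freqs)
    if (o == 0) expect_equal(v, 0) else expect_lt(abs(v - o) / o, 1e-12)
  }
})

test_that("evidence-set probabilities sum to one over the locus universe", {
  withr::local_seed(29)
  for (i in 1:20) {
    n <- sample(3:4, 1)
    labels <- LETTERS[1:n]
    g <- stats::rgamma(n, 1)
    ft <- frequency_table(list(L = stats::setNames(g / sum(g), labels)))
    pick <- function() genotype("L", sample(labels, 1), sample(labels, 1))
    m <- pick(); g1 <- pick(); g2 <- pick()
    params <- mixture_params(d1 = stats::runif(1, 0, 0.9),
                             d2 = stats::runif(1, 0, 0.9),
                             dropin = stats::runif(1, 0, 0.5))
    subsets <- unlist(lapply(0:n, function(k)
      utils::combn(labels, k, simplify = FALSE)), recursive = FALSE)
    tot <- sum(vapply(subsets, function(E)
      mixture_likelihood(E, m, g1, g2, params, ft), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("locus likelihood matches the genotype-enumeration oracle", {
  withr::local_seed(31)
  for (i in 1:40) {
    inst <- rand_instance()
    for (hyp in c("H1", "H2", "H3")) {
      v <- locus_likelihood(inst$E, inst$mother, inst$af, hyp, inst$params,
                            inst$freqs)
      o <- oracle_locus(inst$E, inst$mother, inst$af, hyp, inst$params,
                        inst$freqs)
      if (o == 0) expect_equal(v, 0) else expect_lt(abs(v - o) / o, 1e-12)
    }
  }
})

test_that("H2 labeling average is symmetric when d1 = d2", {
  ft <- toy_freqs()
  m <- genotype("L1", "A", "B")
  af <- genotype("L1", "C", "D")
  p <- mixture_params(d1 = 0.2, d2 = 0.2)
  # with equal dropout, swapping which twin the AF fathered cannot matter;
  # H2 must equal the likelihood computed under either fixed labeling
  eng_h2 <- locus_likelihood(c("A", "B", "C"), m, af, "H2", p, ft)
  pr_af <- child_genotype_prior(m, af, ft, p)
  pr_pop <- child_genotype_prior(m, "POPULATION", ft, p)
  gt <- function(r) genotype("L1", r[["allele1"]], r[["allele2"]])
  lab1 <- 0
  for (i in seq_len(nrow(pr_af))) for (j in seq_len(nrow(pr_pop)))
    lab1 <- lab1 + pr_af$prob[i] * pr_pop$prob[j] *
      mixture_likelihood(c("A", "B", "C"), m, gt(pr_af[i, ]),
                         gt(pr_pop[j, ]), p, ft)
  expect_equal(eng_h2, lab1, tolerance = 1e-12)
})

test_that("apparent exclusions are penalized but kept finite by mutation", {
  ft <- toy_freqs()
  m <- genotype("L1", "A", "B")
  af <- genotype("L1", "C", "C")
  p <- mixture_params(d1 = 0.001, d2 = 0.001, dropin = 0)
  # AF homozygous C: both children must carry C, which is unobserved
  l1 <- locus_likelihood(c("A", "B"), m, af, "H1", p, ft)
  l3 <- locus_likelihood(c("A", "B"), m, af, "H3", p, ft)
  expect_gt(l1, 0)
  expect_lt(l1, l3)
})

test_that("compute_lr sums per-locus log10 LRs and keeps the LR identity", {
  withr::local_seed(37)
  freqs <- simulate_frequencies(n_loci = 12, seed = 41)
  sc <- sim_scenario(n_loci = 12, zygosity = "DZ", paternity = "AF_BOTH",
                     ff_twin1 = 0.05, ff_twin2 = 0.08, seed = 43)
  tr <- simulate_family(freqs, sc)
  cc <- call_case(simulate_plasma(tr), tr$mother)
  grid <- default_dropout_grid(c(0.001, 0.1, 0.5, 0.9))
  lr <- compute_lr(cc, tr$mother, tr$af, freqs, grid = grid)
  # cumulative = sum of per-locus values
  for (g in seq_len(nrow(grid)))
    expect_equal(unname(lr$cumulative_log10[g, ]),
                 unname(colSums(lr$per_locus_log10[, , g])))
  # log10 LR(H1,H3) = log10 LR(H1,H2) + log10 LR(H2,H3) everywhere
  dev <- lr$per_locus_log10[, "lr_h1_h3", ] -
    lr$per_locus_log10[, "lr_h1_h2", ] - lr$per_locus_log10[, "lr_h2_h3", ]
  expect_lt(max(abs(dev)), 1e-9)
  # single locus: cumulative equals the per-locus value
  ev <- evidence_from_calls(cc)[1]
  lr1 <- compute_lr(ev, tr$mother, tr$af, freqs, grid = grid)
  expect_equal(unname(lr1$cumulative_log10[, "lr_h1_h3"]),
               unname(lr1$per_locus_log10[1, "lr_h1_h3", ]))
})

test_that("adding a concordant locus never decreases cumulative LR(H1,H3)", {
  ft <- frequency_table(list(L1 = c(A = 0.4, B = 0.3, C = 0.3),
                             L2 = c(A = 0.4, B = 0.3, C = 0.3)))
  mo <- genotype_profile("m", list(genotype("L1", "A", "A"),
                                   genotype("L2", "A", "A")))
  af <- genotype_profile("f", list(genotype("L1", "C", "C"),
                                   genotype("L2", "C", "C")))
  grid <- default_dropout_grid(c(0.001, 0.1, 0.3))
  lr_one <- compute_lr(list(L1 = c("A", "C")), mo, af, ft, grid = grid)
  lr_two <- compute_lr(list(L1 = c("A", "C"), L2 = c("A", "C")), mo, af, ft,
                       grid = grid)
  expect_true(all(lr_two$cumulative_log10[, "lr_h1_h3"] >=
                  lr_one$cumulative_log10[, "lr_h1_h3"]))
})

test_that("theta zero gives Hardy-Weinberg; theta > 0 follows Balding-Nichols", {
  ft <- frequency_table(list(L1 = c(A = 0.4, B = 0.3, C = 0.2, D = 0.1)))
  m <- genotype("L1", "A", "B")
  p0 <- mixture_params(mutation_rate = 0, theta = 0)
  pt <- mixture_params(mutation_rate = 0, theta = 0.05)
  pr0 <- child_genotype_prior(m, "POPULATION", ft, p0)
  # maternal transmission is 1/2 A, 1/2 B, so P({A,C}) = 1/2 * p(C)
  prob_of <- function(pr, a1, a2) {
    k <- pr$allele1 == min(a1, a2) & pr$allele2 == max(a1, a2)
    if (any(k)) pr$prob[k] else 0
  }
  expect_equal(prob_of(pr0, "A", "C"), 0.5 * 0.2 + 0, tolerance = 1e-12)
  prt <- child_genotype_prior(m, "POPULATION", ft, pt)
  # Balding-Nichols conditional on the maternal alleles {A, B}:
  # p'(C) = (0 * theta + (1 - theta) * 0.2) / (1 + (2 - 1) * theta)
  pC <- (1 - 0.05) * 0.2 / (1 + 0.05)
  pA <- (1 * 0.05 + (1 - 0.05) * 0.4) / (1 + 0.05)
  expect_equal(prob_of(prt, "A", "C") / 0.5, pC, tolerance = 1e-12)
  expect_gt(pA, 0.4)  # theta pulls toward alleles already seen
  expect_equal(prob_of(prt, "B", "C") / 0.5, pC, tolerance = 1e-12)
})

test_that("specificity screen flags the true father and not unrelated men", {
  withr::local_seed(47)
  freqs <- simulate_frequencies(n_loci = 25, seed = 53)
  sc <- sim_scenario(n_loci = 25, zygosity = "DZ", paternity = "AF_BOTH",
                     ff_twin1 = 0.05, ff_twin2 = 0.08, mean_depth = 2000,
                     seed = 59)
  tr <- simulate_family(freqs, sc)
  cc <- call_case(simulate_plasma(tr), tr$mother)
  # unrelated candidates: fresh Hardy-Weinberg draws
  unrel <- lapply(1:5, function(i) {
    sc2 <- sim_scenario(n_loci = 25, seed = 700 + i)
    simulate_family(freqs, sc2)$af
  })
  cands <- c(list(tr$af), unrel)
  grid <- default_dropout_grid(c(0.001, 0.05, 0.1, 0.2, 0.3))
  scr <- specificity_screen(cc, tr$mother, cands, freqs, grid = grid)
  expect_equal(nrow(scr), 6L)
  expect_gt(scr$min_log10_lr_h1_h3[1], 0)     # true father included
  expect_true(all(scr$max_log10_lr_h1_h3[-1] < 0))  # unrelated excluded
  expect_error(specificity_screen(cc, tr$mother, list(), freqs), "empty")
})
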