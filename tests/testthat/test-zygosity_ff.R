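# Builds an mh_case_calls object from explicit per-locus specifications:
# each element is list(maternal counts..., nonmaternal depths) via a plasma
# counts + maternal genotype pair.
calls_from <- function(case_id, loci) {
  pl <- plasma_profile(case_id, lapply(names(loci), function(loc) {
    plasma_counts(loc, loci[[loc]]$depths)
  }))
  mat <- genotype_profile("m", lapply(names(loci), function(loc) {
    g <- loci[[loc]]$maternal
    genotype(loc, g[1], g[2])
  }))
  call_case(pl, mat)
}

test_that("zygosity follows the informative-locus rule", {
  dz <- calls_from("dz", list(
    La = list(depths = c(A = 900L, B = 50L, C = 50L), maternal = c("A", "A")),
    Lb = list(depths = c(A = 1000L), maternal = c("A", "A"))))
  z <- call_zygosity(dz)
  expect_equal(z$call, "DZ")
  expect_equal(z$informative_loci, "La")
  mz <- calls_from("mz", list(
    La = list(depths = c(A = 950L, B = 50L), maternal = c("A", "A"))))
  expect_equal(call_zygosity(mz)$call, "MZ")
  # threshold respected: one informative locus is not enough at min 2
  expect_equal(call_zygosity(dz, min_informative = 2)$call, "MZ")
  # count interface mirrors the rule
  expect_equal(call_zygosity(0)$call, "MZ")
  expect_equal(call_zygosity(3)$call, "DZ")
})

test_that("DZ fetal fractions follow 2d/D averaged over informative loci", {
  one <- calls_from("c1", list(
    L1 = list(depths = c(A = 92L, B = 3L, C = 5L), maternal = c("A", "A"))))
  ff <- estimate_ff_dz(one)
  expect_equal(ff$ff_lower, 0.06)
  expect_equal(ff$ff_higher, 0.10)
  expect_equal(ff$ff_combined, 0.16)
  two <- calls_from("c2", list(
    L1 = list(depths = c(A = 92L, B = 3L, C = 5L), maternal = c("A", "A")),
    L2 = list(depths = c(A = 184L, B = 6L, C = 10L), maternal = c("A", "A"))))
  ff2 <- estimate_ff_dz(two)
  expect_equal(ff2$ff_lower, 0.06)
  expect_equal(ff2$ff_higher, 0.10)
  # Type II loci are excluded from the DZ estimate
  mixed <- calls_from("c3", list(
    L1 = list(depths = c(A = 92L, B = 3L, C = 5L), maternal = c("A", "A")),
    L2 = list(depths = c(A = 900L, B = 100L), maternal = c("A", "A"))))
  expect_equal(estimate_ff_dz(mixed)$n_loci_used, 1L)
  # no informative locus -> directed error
  t2only <- calls_from("c4", list(
    L1 = list(depths = c(A = 940L, B = 60L), maternal = c("A", "A"))))
  expect_error(estimate_ff_dz(t2only), "estimate_ff_mz")
})

test_that("MZ combined FF averages 2d/D over Type II loci", {
  one <- calls_from("m1", list(
    L1 = list(depths = c(A = 94L, B = 6L), maternal = c("A", "A"))))
  expect_equal(estimate_ff_mz(one)$ff_combined, 0.12)
  expect_true(is.na(estimate_ff_mz(one)$ff_lower))
  two <- calls_from("m2", list(
    L1 = list(depths = c(A = 95L, B = 5L), maternal = c("A", "A")),
    L2 = list(depths = c(A = 93L, B = 7L), maternal = c("A", "A"))))
  expect_equal(estimate_ff_mz(two)$ff_combined, 0.12)
  t1only <- calls_from("m3", list(
    L1 = list(depths = c(A = 100L), maternal = c("A", "A"))))
  expect_error(estimate_ff_mz(t1only), "no Type II locus")
})

test_that("combined FF conservation and ordering hold on simulated DZ cases", {
  withr::local_seed(77)
  freqs <- simulate_frequencies(n_loci = 30, seed = 31)
  for (s in 1:15) {
    sc <- sim_scenario(n_loci = 30, zygosity = "DZ", paternity = "AF_BOTH",
                       ff_twin1 = stats::runif(1, 0.03, 0.08),
                       ff_twin2 = stats::runif(1, 0.05, 0.2),
                       mean_depth = 2000, seed = 400 + s)
    tr <- simulate_family(freqs, sc)
    cc <- call_case(simulate_plasma(tr), tr$mother)
    if (case_summary(cc)$n_informative == 0) next
    ff <- estimate_ff_dz(cc)
    expect_identical(ff$ff_combined, ff$ff_lower + ff$ff_higher)
    expect_lte(ff$ff_lower, ff$ff_higher)
  }
})

test_that("min/max depth ordering inflates the higher FF when true FFs are equal", {
  # This is the stated assumption of the estimator, not a defect: when the
  # two fetuses contribute equally, per-locus ordering by depth assigns
  # sampling noise asymmetrically.
  freqs <- simulate_frequencies(seed = 101)
  lows <- highs <- c()
  for (s in 1:25) {
    sc <- sim_scenario(zygosity = "DZ", paternity = "AF_BOTH",
                       ff_twin1 = 0.06, ff_twin2 = 0.06, mean_depth = 2000,
                       depth_dispersion = 0, seed = 3000 + s)
    tr <- simulate_family(freqs, sc)
    cc <- call_case(simulate_plasma(tr), tr$mother)
    if (case_summary(cc)$n_informative == 0) next
    ff <- estimate_ff_dz(cc)
    lows <- c(lows, ff$ff_lower); highs <- c(highs, ff$ff_higher)
  }
  expect_lt(mean(lows), 0.06)
  expect_gt(mean(highs), 0.06)
})

test_that("validation counts dropouts, drop-ins and real informative loci", {
  # construct a case where truth and calls are known exactly
  cc <- calls_from("v1", list(
    L1 = list(depths = c(A = 900L, B = 50L, C = 50L), maternal = c("A", "A")),
    L2 = list(depths = c(A = 960L, D = 40L), maternal = c("A", "A")),
    L3 = list(depths = c(A = 970L, E = 30L), maternal = c("A", "A"))))
  mat <- genotype_profile("m", list(genotype("L1", "A", "A"),
                                    genotype("L2", "A", "A"),
                                    genotype("L3", "A", "A")))
  f1 <- genotype_profile("f1", list(genotype("L1", "A", "B"),
                                    genotype("L2", "A", "D"),
                                    genotype("L3", "A", "F")))
  f2 <- genotype_profile("f2", list(genotype("L1", "A", "C"),
                                    genotype("L2", "A", "D"),
                                    genotype("L3", "A", "A")))
  v <- validate_against_fetal_genotypes(cc, f1, f2, mat)
  # real PAs: L1 {B, C}, L2 {D}, L3 {F} -> 4; F dropped out; E dropped in
  expect_equal(v$n_real_pa, 4L)
  expect_equal(v$n_dropout, 1L)
  expect_equal(v$n_dropin, 1L)
  expect_equal(v$detection_rate, 3 / 4)
  expect_equal(v$n_real_informative, 1L)
  # validated per-fetus FFs from the true assignment at L1
  expect_equal(v$ff_lower, 0.10)
  expect_equal(v$ff_higher, 0.10)
  # perfect agreement: calls identical to truth
  cc2 <- calls_from("v2", list(
    L1 = list(depths = c(A = 900L, B = 50L, C = 50L), maternal = c("A", "A"))))
  v2 <- validate_against_fetal_genotypes(
    cc2,
    genotype_profile("f1", list(genotype("L1", "A", "B"))),
    genotype_profile("f2", list(genotype("L1", "A", "C"))),
    genotype_profile("m", list(genotype("L1", "A", "A"))))
  expect_equal(v2$n_dropout, 0L)
  expect_equal(v2$n_dropin, 0L)
  expect_equal(v2$detection_rate, 1)
})

test_that("FF concordance is the squared Pearson correlation", {
  est <- data.frame(case_id = 1:5, ff_lower = c(1, 2, 3, 4, 5),
                    ff_higher = c(2, 4, 5, 8, 10),
                    ff_combined = c(3, 6, 8, 12, 15))
  # identical vectors -> R^2 = 1
  r2 <- ff_concordance(est, est)
  expect_equal(unname(r2), c(1, 1, 1))
  # random uncorrelated vectors -> R^2 near 0 at large n
  withr::local_seed(8)
  n <- 4000
  a <- data.frame(case_id = 1:n, ff_lower = stats::rnorm(n),
                  ff_higher = stats::rnorm(n), ff_combined = stats::rnorm(n))
  b <- data.frame(case_id = 1:n, ff_lower = stats::rnorm(n),
                  ff_higher = stats::rnorm(n), ff_combined = stats::rnorm(n))
  expect_lt(max(ff_concordance(a, b)), 0.01)
  expect_error(ff_concordance(est[1:2, ], est[1:2, ]), "at least 3")
  flat <- est; flat$ff_lower <- 1
  expect_error(ff_concordance(flat, flat), "zero variance")
})

test_that("FF ratio is higher over lower", {
  ff <- structure(list(case_id = "x", ff_lower = 0.05, ff_higher = 0.10,
                       ff_combined = 0.15, n_loci_used = 4L, zygosity = "DZ"),
                  class = "mh_ff")
  expect_equal(ff_ratio(ff), 2)
  ff$ff_higher <- 0.05
  expect_equal(ff_ratio(ff), 1)
  ff$ff_lower <- 0
  expect_error(ff_ratio(ff), "zero")
  ff$ff_lower <- NA_real_
  expect_error(ff_ratio(ff), "absent")
})

test_that("simulated DZ ratio recovers the true contribution ratio", {
  freqs <- simulate_frequencies(seed = 55)
  ratios <- c()
  for (s in 1:10) {
    sc <- sim_scenario(zygosity = "DZ", paternity = "AF_BOTH",
                       ff_twin1 = 0.04, ff_twin2 = 0.08, mean_depth = 20000,
                       depth_dispersion = 0, seed = 600 + s)
    tr <- simulate_family(freqs, sc)
    cc <- call_case(simulate_plasma(tr), tr$mother)
    if (case_summary(cc)$n_informative == 0) next
    ratios <- c(ratios, ff_ratio(estimate_ff_dz(cc)))
  }
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})
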