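#' Simulation scenario for a twin cfDNA sequencing experiment
#'
#' Bundles the study conditions emulated by the generator: a multiallelic
#' microhaplotype panel, a twin family (monozygotic or dizygotic, with the
#' alleged father being the father of both, one, or neither twin), per-fetus
#' fetal fractions, and the read-count noise model.
#'
#' @param n_loci Panel size. Default 60.
#' @param alleles_per_locus Integer vector of allowed allele counts per locus
#'   (one value is drawn per locus). Default `4:8`.
#' @param zygosity `"DZ"` or `"MZ"`.
#' @param paternity `"AF_BOTH"` (alleged father fathered both twins, H1),
#'   `"HS"` (heteropaternal superfecundation, H2), or `"NEITHER"` (random
#'   father(s), H3; the alleged-father profile is then an unrelated man).
#' @param ff_twin1,ff_twin2 True fetal fractions. Defaults 0.05 and 0.09,
#'   typical of dizygotic twin plasma (lower FF roughly 3-8%, higher roughly
#'   5-20%). For MZ scenarios `ff_twin1` is the combined fetal fraction and
#'   `ff_twin2` is ignored.
#' @param mean_depth Mean total read depth per locus. Default 2000.
#' @param depth_dispersion Negative-binomial dispersion of total depth
#'   (variance = mu + dispersion * mu^2); 0 gives constant depth. Default 0.1.
#' @param dropin_rate Per-locus probability of one spurious low-level allele
#'   (simulated at a 0.5-1.5% read ratio, drawn by population frequency).
#'   Default 0.
#' @param dropout_sim Per-fetal-allele-copy probability that the copy
#'   contributes no reads. Default 0.
#' @param seed Integer seed; all randomness of the scenario flows from it.
#' @return An object of class `mh_scenario`.
#' @export
sim_scenario <- function(n_loci = 60L, alleles_per_locus = 4:8,
                         zygosity = c("DZ", "MZ"),
                         paternity = c("AF_BOTH", "HS", "NEITHER"),
                         ff_twin1 = 0.05, ff_twin2 = 0.09,
                         mean_depth = 2000L, depth_dispersion = 0.1,
                         dropin_rate = 0, dropout_sim = 0, seed = 1L) {
  zygosity <- match.arg(zygosity)
  paternity <- match.arg(paternity)
  if (zygosity == "MZ" && paternity == "HS")
    stop("monozygotic twins cannot be heteropaternal")
  if (zygosity == "DZ" && ff_twin1 + ff_twin2 >= 1)
    stop("ff_twin1 + ff_twin2 must be below 1")
  if (zygosity == "MZ" && ff_twin1 >= 1)
    stop("combined fetal fraction must be below 1")
  structure(list(n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 zygosity = zygosity, paternity = paternity,
                 ff_twin1 = ff_twin1, ff_twin2 = ff_twin2,
                 mean_depth = as.integer(mean_depth),
                 depth_dispersion = depth_dispersion,
                 dropin_rate = dropin_rate, dropout_sim = dropout_sim,
                 seed = as.integer(seed)),
            class = "mh_scenario")
}

#' Simulate a microhaplotype panel frequency table
#'
#' Per-locus allele frequencies are drawn from a flat Dirichlet and sum to 1.
#' Allele labels are 3-SNP haplotype strings.
#'
#' @param n_loci Number of loci.
#' @param alleles_per_locus Allowed allele counts (sampled per locus).
#' @param seed Integer seed.
#' @param unseen_freq Unseen-allele floor for the resulting table.
#' @return An `mh_freqs` table.
#' @export
simulate_frequencies <- function(n_loci = 60L, alleles_per_locus = 4:8,
                                 seed = 1L, unseen_freq = 0.002) {
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (any(alleles_per_locus < 2L)) stop("alleles_per_locus must be >= 2")
  withr::local_seed(seed)
  haplos <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0,
                  collapse = "")
  entries <- lapply(seq_len(n_loci), function(i) {
    k <- if (length(alleles_per_locus) == 1L) alleles_per_locus
         else sample(alleles_per_locus, 1L)
    labels <- sort(sample(haplos, k))
    g <- stats::rgamma(k, shape = 1)
    stats::setNames(g / sum(g), labels)
  })
  names(entries) <- sprintf("MH-%02d", seq_len(n_loci))
  frequency_table(entries, unseen_freq = unseen_freq)
}

#' Simulate a twin family with known ground truth
#'
#' Parents are drawn under Hardy-Weinberg from the panel frequencies; twins
#' are drawn by Mendelian transmission according to the scenario's zygosity
#' and paternity. The returned truth ledger records everything downstream
#' stages estimate: genotypes of every family member, the real
#' fetus-specific (paternal) allele set per locus, the true informative
#' loci, loci where a fetus is homozygous for a nonmaternal allele (these
#' violate the one-copy assumption of the fetal-fraction estimator), and
#' the true fetal fractions.
#'
#' @param freqs An `mh_freqs` panel table.
#' @param scenario An `mh_scenario`.
#' @return An object of class `mh_truth` with fields `mother`, `af`,
#'   `random_men` (list), `twin1`, `twin2` (`mh_profile`s), `real_pa`
#'   (named list locus -> character), `informative_loci`,
#'   `homozygous_nonmaternal_loci`, `scenario`.
#' @export
simulate_family <- function(freqs, scenario) {
  stopifnot(inherits(freqs, "mh_freqs"), inherits(scenario, "mh_scenario"))
  withr::local_seed(scenario$seed + 1L)
  loci <- panel_loci(freqs)
  hw_draw <- function(id) {
    gts <- lapply(loci, function(loc) {
      p <- freqs$entries[[loc]]
      a <- sample(names(p), 2L, replace = TRUE, prob = p)
      genotype(loc, a[1], a[2])
    })
    genotype_profile(id, gts)
  }
  mother <- hw_draw("mother")
  af <- hw_draw("af")
  rm1 <- hw_draw("rm1")
  rm2 <- hw_draw("rm2")
  fathers <- switch(scenario$paternity,
                    AF_BOTH = list(af, af),
                    HS = list(af, rm1),
                    NEITHER = list(rm1, rm2))
  child_draw <- function(id, father) {
    gts <- lapply(loci, function(loc) {
      ma <- sample(mother$genotypes[[loc]]$alleles, 1L)
      pa <- sample(father$genotypes[[loc]]$alleles, 1L)
      genotype(loc, ma, pa)
    })
    genotype_profile(id, gts)
  }
  twin1 <- child_draw("twin1", fathers[[1]])
  twin2 <- if (scenario$zygosity == "MZ") {
    genotype_profile("twin2", unname(twin1$genotypes))
  } else {
    child_draw("twin2", fathers[[2]])
  }
  real_pa <- lapply(loci, function(loc) {
    mat <- mother$genotypes[[loc]]$alleles
    union(setdiff(twin1$genotypes[[loc]]$alleles, mat),
          setdiff(twin2$genotypes[[loc]]$alleles, mat))
  })
  names(real_pa) <- loci
  informative <- loci[vapply(real_pa, length, integer(1)) == 2L]
  homo_nm <- loci[vapply(loci, function(loc) {
    mat <- mother$genotypes[[loc]]$alleles
    any(vapply(list(twin1, twin2), function(tw) {
      al <- tw$genotypes[[loc]]$alleles
      al[1] == al[2] && !(al[1] %in% mat)
    }, logical(1)))
  }, logical(1))]
  out <- structure(list(mother = mother, af = af, random_men = list(rm1, rm2),
                        twin1 = twin1, twin2 = twin2, real_pa = real_pa,
                        informative_loci = informative,
                        homozygous_nonmaternal_loci = homo_nm,
                        scenario = scenario),
                   class = "mh_truth")
  # the plasma simulator draws drop-in alleles from the panel frequencies
  attr(out, "panel_freqs") <- freqs
  out
}

#' Simulate a maternal plasma read-count profile
#'
#' Per locus, total depth is drawn around `mean_depth` (negative binomial
#' with the scenario's dispersion; constant when dispersion is 0). Expected
#' allele proportions: the mother contributes `1 - FF_total` split equally
#' over her two allele copies; each fetus contributes its fetal fraction
#' split equally over its two copies (for MZ twins, a single fetal
#' contribution of the combined FF). Optional dropout zeroes individual
#' fetal allele copies; optional drop-in adds one spurious allele at a
#' 0.5-1.5% ratio. Counts are multinomial.
#'
#' @param truth An `mh_truth` ledger from [simulate_family()].
#' @param scenario The matching `mh_scenario` (defaults to the one recorded
#'   in `truth`).
#' @param case_id Case label. Default `"sim"`.
#' @return An `mh_plasma` profile.
#' @export
simulate_plasma <- function(truth, scenario = truth$scenario,
                            case_id = "sim") {
  stopifnot(inherits(truth, "mh_truth"), inherits(scenario, "mh_scenario"))
  withr::local_seed(scenario$seed + 2L)
  mz <- scenario$zygosity == "MZ"
  ff1 <- scenario$ff_twin1
  ff2 <- if (mz) 0 else scenario$ff_twin2
  ff_total <- ff1 + ff2
  loci <- names(truth$mother$genotypes)
  counts <- lapply(loci, function(loc) {
    mass <- numeric(0)
    add <- function(mass, alleles, weight_per_copy, dropout) {
      for (a in alleles) {
        w <- weight_per_copy
        if (dropout > 0 && stats::runif(1) < dropout) w <- 0
        mass[a] <- (if (a %in% names(mass)) mass[[a]] else 0) + w
      }
      mass
    }
    mass <- add(mass, truth$mother$genotypes[[loc]]$alleles,
                (1 - ff_total) / 2, 0)
    mass <- add(mass, truth$twin1$genotypes[[loc]]$alleles, ff1 / 2,
                scenario$dropout_sim)
    if (!mz)
      mass <- add(mass, truth$twin2$genotypes[[loc]]$alleles, ff2 / 2,
                  scenario$dropout_sim)
    if (scenario$dropin_rate > 0 && stats::runif(1) < scenario$dropin_rate) {
      p <- freq_drop_candidates(truth, loc, names(mass))
      if (length(p)) {
        spurious <- sample(names(p), 1L, prob = p)
        u <- stats::runif(1, 0.005, 0.015)
        mass <- mass / sum(mass) * (1 - u)
        mass[spurious] <- u
      }
    }
    depth <- if (scenario$depth_dispersion == 0) scenario$mean_depth
             else stats::rnbinom(1L, mu = scenario$mean_depth,
                                 size = 1 / scenario$depth_dispersion)
    if (depth == 0 || sum(mass) == 0)
      return(plasma_counts(loc, stats::setNames(integer(0), character(0))))
    draw <- stats::rmultinom(1L, depth, prob = mass / sum(mass))[, 1]
    plasma_counts(loc, stats::setNames(as.integer(draw), names(mass)))
  })
  plasma_profile(case_id, counts)
}

# Population frequencies of alleles at `loc` not already contributing mass;
# used to draw a spurious drop-in allele. The panel table travels with the
# truth ledger (attached by simulate_family).
freq_drop_candidates <- function(truth, loc, present) {
  tab <- attr(truth, "panel_freqs")
  if (is.null(tab)) return(NULL)
  p <- tab$entries[[loc]]
  p <- p[setdiff(names(p), present)]
  if (length(p) == 0L) return(NULL)
  p / sum(p)
}

#' Generate a cohort of simulated twin cases
#'
#' Draws one shared panel frequency table and one family + plasma profile per
#' scenario, optionally writing the standard TSV bundle (frequency table,
#' genotype profiles of every family member, plasma counts) plus a JSON truth
#' ledger to a directory. All randomness derives from `seed`; per-case seeds
#' are `seed + case index`.
#'
#' @param scenarios List of `mh_scenario` objects (their `seed` fields are
#'   overwritten by the derived per-case seeds).
#' @param seed Master seed.
#' @param outdir Optional output directory (created if needed).
#' @param panel_seed Seed for the shared frequency panel; defaults to `seed`.
#' @return Invisibly, a list with `freqs`, `plasma` (list of `mh_plasma`),
#'   `truths` (list of `mh_truth`) and, when `outdir` is given, `paths`.
#' @export
generate_cohort <- function(scenarios, seed = 1L, outdir = NULL,
                            panel_seed = seed) {
  stopifnot(length(scenarios) >= 1L)
  sc1 <- scenarios[[1]]
  freqs <- simulate_frequencies(sc1$n_loci, sc1$alleles_per_locus,
                                seed = panel_seed)
  truths <- list(); plasma <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    sc$seed <- as.integer(seed + i)
    truth <- simulate_family(freqs, sc)
    case_id <- sprintf("case%02d", i)
    truths[[case_id]] <- truth
    plasma[[case_id]] <- simulate_plasma(truth, sc, case_id = case_id)
  }
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(freqs = file.path(outdir, "freqs.tsv"),
                  genotypes = file.path(outdir, "genotypes.tsv"),
                  plasma = file.path(outdir, "plasma.tsv"),
                  truth = file.path(outdir, "truth.json"))
    write_frequency_table(freqs, paths$freqs)
    profs <- unlist(lapply(names(truths), function(cid) {
      tr <- truths[[cid]]
      members <- list(tr$mother, tr$af, tr$twin1, tr$twin2)
      lapply(members, function(pr) {
        genotype_profile(paste0(cid, "_", pr$sample_id),
                         unname(pr$genotypes))
      })
    }), recursive = FALSE)
    write_genotype_profiles(profs, paths$genotypes)
    write_plasma_profiles(plasma, paths$plasma)
    truth_json <- lapply(truths, function(tr) {
      list(zygosity = tr$scenario$zygosity,
           paternity = tr$scenario$paternity,
           ff_twin1 = tr$scenario$ff_twin1,
           ff_twin2 = if (tr$scenario$zygosity == "MZ") NULL
                      else tr$scenario$ff_twin2,
           informative_loci = tr$informative_loci,
           real_pa = tr$real_pa)
    })
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(list(freqs = freqs, plasma = plasma, truths = truths,
                 paths = paths))
}
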