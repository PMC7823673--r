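#!/usr/bin/env Rscript
# Estimate fetal fractions for every simulated case (per-fetus for DZ,
# combined-only for MZ), validate the calls against the fetal reference
# genotypes, and measure estimated-vs-validated concordance (R^2) across
# DZ cases. Writes results/fetal_fraction.tsv.

suppressPackageStartupMessages(library(twinhap))

plasma <- read_plasma_profiles("results/sim/plasma.tsv")
profiles <- read_genotype_profiles("results/sim/genotypes.tsv")
truth <- read_report("results/sim/truth.json")

rows <- lapply(names(plasma), function(cid) {
  mother <- profiles[[paste0(cid, "_mother")]]
  cc <- call_case(plasma[[cid]], mother)
  z <- call_zygosity(cc)
  ff <- estimate_ff(cc, z)
  v <- validate_against_fetal_genotypes(cc, profiles[[paste0(cid, "_twin1")]],
                                        profiles[[paste0(cid, "_twin2")]],
                                        mother)
  tr <- truth[[cid]]
  true_ffs <- sort(c(tr$ff_twin1, if (!is.null(tr$ff_twin2)) tr$ff_twin2))
  data.frame(case_id = cid, zygosity = z$call,
             est_ff_lower = ff$ff_lower, est_ff_higher = ff$ff_higher,
             est_ff_combined = ff$ff_combined,
             val_ff_lower = v$ff_lower, val_ff_higher = v$ff_higher,
             val_ff_combined = v$ff_combined,
             true_ff_lower = if (length(true_ffs) == 2) true_ffs[1] else NA,
             true_ff_combined = sum(true_ffs),
             detection_rate = v$detection_rate,
             n_dropout = v$n_dropout, n_dropin = v$n_dropin,
             stringsAsFactors = FALSE)
})
tab <- do.call(rbind, rows)
write_report(tab, "results/fetal_fraction.tsv")
cat("Fetal fractions written to results/fetal_fraction.tsv\n")

dz <- tab[tab$zygosity == "DZ", ]
est <- data.frame(case_id = dz$case_id, ff_lower = dz$est_ff_lower,
                  ff_higher = dz$est_ff_higher,
                  ff_combined = dz$est_ff_combined)
val <- data.frame(case_id = dz$case_id, ff_lower = dz$val_ff_lower,
                  ff_higher = dz$val_ff_higher,
                  ff_combined = dz$val_ff_combined)
r2 <- ff_concordance(est, val)
cat(sprintf("  estimated vs validated R^2: lower %.3f, higher %.3f, combined %.3f\n",
            r2["r2_lower"], r2["r2_higher"], r2["r2_combined"]))
cat(sprintf("  detection rate range: %s%% - %s%%\n",
            format_percent(min(tab$detection_rate)),
            format_percent(max(tab$detection_rate))))
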