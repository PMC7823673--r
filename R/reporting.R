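#' Run configuration for a full case analysis
#'
#' Collects every tunable of the pipeline in one serializable record; JSON
#' round-trips via [write_report()] / [read_report()] and
#' [run_config_from_list()].
#'
#' @param threshold Nonmaternal-allele detection threshold. Default 0.01.
#' @param min_depth Per-locus depth QC. Default 50.
#' @param min_informative Informative loci required for a DZ call. Default 1.
#' @param grid Dropout grid (data.frame `d1`, `d2`).
#' @param dropin,mutation_rate,theta Mixture-model parameters (see
#'   [mixture_params()]).
#' @param seed Optional integer seed echoed into reports.
#' @return An object of class `mh_config` (a named list).
#' @export
run_config <- function(threshold = 0.01, min_depth = 50L,
                       min_informative = 1L,
                       grid = default_dropout_grid(),
                       dropin = 0.01, mutation_rate = 1e-8, theta = 0,
                       seed = NULL) {
  structure(list(threshold = threshold, min_depth = as.integer(min_depth),
                 min_informative = as.integer(min_informative),
                 grid = as.data.frame(grid),
                 dropin = dropin, mutation_rate = mutation_rate,
                 theta = theta, seed = seed),
            class = "mh_config")
}

#' Rebuild an `mh_config` from a parsed JSON list
#' @param x A list as returned by [read_report()] on a config written with
#'   [write_report()].
#' @return An `mh_config`.
#' @export
run_config_from_list <- function(x) {
  run_config(threshold = x$threshold, min_depth = x$min_depth,
             min_informative = x$min_informative,
             grid = as.data.frame(x$grid),
             dropin = x$dropin, mutation_rate = x$mutation_rate,
             theta = x$theta, seed = x$seed)
}

#' Full analysis of one twin plasma case
#'
#' Runs the pipeline stages in order: nonmaternal allele calls, zygosity,
#' fetal fraction, paternity likelihood ratios (when an alleged-father
#' profile and a frequency table are supplied), and validation against fetal
#' reference genotypes (when supplied). Zygosity and fetal fraction do not
#' require a paternal sample; the LR stage is skipped with a warning when
#' it is missing.
#'
#' @param plasma An `mh_plasma` profile.
#' @param maternal The mother's `mh_profile`.
#' @param freqs An `mh_freqs` table (needed for the LR stage).
#' @param af Optional alleged-father `mh_profile`.
#' @param fetal1,fetal2 Optional fetal reference `mh_profile`s.
#' @param config An `mh_config`.
#' @return An object of class `mh_report`: `case_id`, `config`, `summary`
#'   (from [case_summary()]), `zygosity`, `ff`, `lr` (or `NULL`),
#'   `validation` (or `NULL`), and `row` - a one-row data.frame mirroring
#'   the package's cohort report columns.
#' @export
run_case <- function(plasma, maternal, freqs = NULL, af = NULL,
                     fetal1 = NULL, fetal2 = NULL, config = run_config()) {
  calls <- call_case(plasma, maternal, threshold = config$threshold,
                     min_depth = config$min_depth)
  zyg <- call_zygosity(calls, min_informative = config$min_informative)
  ff <- estimate_ff(calls, zyg)
  lr <- NULL
  if (!is.null(af) && !is.null(freqs)) {
    params <- mixture_params(dropin = config$dropin,
                             mutation_rate = config$mutation_rate,
                             theta = config$theta)
    lr <- compute_lr(calls, maternal, af, freqs, grid = config$grid,
                     params = params)
  } else {
    warning("case ", plasma$case_id,
            ": alleged-father profile or frequency table missing, ",
            "LR stage skipped")
  }
  validation <- NULL
  if (!is.null(fetal1) && !is.null(fetal2)) {
    validation <- validate_against_fetal_genotypes(calls, fetal1, fetal2,
                                                   maternal)
  }
  s <- case_summary(calls)
  row <- data.frame(
    case_id = plasma$case_id,
    n_locus_pa = s$n_loci_pa,
    n_informative = s$n_informative,
    n_assumed_pa = s$n_assumed_pa,
    zygosity = zyg$call,
    ff_lower = ff$ff_lower,
    ff_higher = ff$ff_higher,
    ff_combined = ff$ff_combined,
    min_log10_lr_h1_h3 = if (is.null(lr)) NA_real_
                         else min(lr$cumulative_log10[, "lr_h1_h3"]),
    max_log10_lr_h1_h3 = if (is.null(lr)) NA_real_
                         else max(lr$cumulative_log10[, "lr_h1_h3"]),
    detection_rate = if (is.null(validation)) NA_real_
                     else validation$detection_rate,
    stringsAsFactors = FALSE
  )
  structure(list(case_id = plasma$case_id, config = config, summary = s,
                 zygosity = zyg, ff = ff, lr = lr, validation = validation,
                 row = row),
            class = "mh_report")
}

#' @export
print.mh_report <- function(x, ...) {
  cat("Case ", x$case_id, ": ", x$zygosity$call, ", combined FF ",
      format_percent(x$ff$ff_combined), "%",
      if (!is.null(x$lr))
        paste0(", cumulative log10 LR(H1,H3) ",
               format_fixed(min(x$lr$cumulative_log10[, "lr_h1_h3"]), 3),
               " to ",
               format_fixed(max(x$lr$cumulative_log10[, "lr_h1_h3"]), 3)),
      "\n", sep = "")
  invisible(x)
}

#' Aggregate case reports into a cohort summary
#'
#' @param reports List of `mh_report` objects.
#' @param truths Optional list of `mh_truth` ledgers (matched by position)
#'   for a zygosity confusion matrix.
#' @return A list: `table` (one row per case), `n_mz`, `n_dz`, `ff_ranges`,
#'   `detection_rate_range` (when validation present), `confusion`
#'   (when truths given).
#' @export
cohort_summary <- function(reports, truths = NULL) {
  stopifnot(length(reports) >= 1L)
  tab <- do.call(rbind, lapply(reports, `[[`, "row"))
  rownames(tab) <- NULL
  calls <- tab$zygosity
  out <- list(table = tab,
              n_mz = sum(calls == "MZ"),
              n_dz = sum(calls == "DZ"),
              ff_ranges = list(
                lower = range(tab$ff_lower, na.rm = TRUE),
                higher = range(tab$ff_higher, na.rm = TRUE),
                combined = range(tab$ff_combined, na.rm = TRUE)))
  if (any(!is.na(tab$detection_rate)))
    out$detection_rate_range <- range(tab$detection_rate, na.rm = TRUE)
  if (!is.null(truths)) {
    truth_z <- vapply(truths, function(t) t$scenario$zygosity, character(1))
    out$confusion <- table(truth = truth_z, called = calls)
  }
  out
}

#' Published 19-case twin cohort summary
#'
#' A transcription of the per-case summary table of a published 19-case
#' microhaplotype NIPT study of twin pregnancies (13 dizygotic, 6
#' monozygotic): assumed-paternal-allele counts, informative-locus counts,
#' estimated fetal fractions, and the validation columns obtained from fetal
#' tissue genotypes (real paternal alleles, dropout/drop-in counts,
#' detection rate, validated fetal fractions). Fetal fractions are in
#' percent as printed; `NA` marks per-fetus fractions of monozygotic cases,
#' where they are not applicable.
#'
#' @return A data.frame, one row per case.
#' @export
example_twin_cohort <- function() {
  path <- system.file("extdata", "twin_cohort_summary.tsv",
                      package = "twinhap", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
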