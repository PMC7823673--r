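#' Per-allele read ratios at a locus
#'
#' The ratio of each allele is its depth divided by the total locus depth
#' `D`, the denominator used both for the nonmaternal-allele detection
#' threshold and for fetal-fraction estimation.
#'
#' @param counts An `mh_counts` object with `total_depth > 0`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
allele_ratios <- function(counts) {
  stopifnot(inherits(counts, "mh_counts"))
  if (counts$total_depth <= 0L)
    stop("locus ", counts$locus_id, ": zero total depth, ratios undefined")
  counts$depth / counts$total_depth
}

#' Detect nonmaternal (assumed paternal) alleles at one locus
#'
#' Plasma alleles absent from the maternal genotype whose read ratio reaches
#' the detection threshold (default 1.0% of total locus depth) are treated as
#' fetal, paternally inherited alleles. The locus is then classified by how
#' many such alleles it shows: Type I (none), Type II (one), Type III (two,
#' the informative pattern for dizygotic twins). More than two nonmaternal
#' alleles can only arise through noise and yields UNCLASSIFIED, as does a
#' locus failing the depth QC.
#'
#' @param counts An `mh_counts` object.
#' @param maternal The mother's `mh_genotype` at the same locus.
#' @param threshold Minimum allele ratio for detection (`>=` comparison).
#'   Default 0.01.
#' @param min_depth Minimum total depth for the locus to pass QC. Default 50.
#' @return An object of class `mh_locus_call` with fields `locus_id`,
#'   `maternal_alleles`, `observed_alleles` (all alleles at or above the
#'   threshold), `nonmaternal` (data.frame allele/depth/ratio, sorted by
#'   depth descending, allele ascending on ties), `pattern_type`
#'   (`"TYPE_I"`, `"TYPE_II"`, `"TYPE_III"`, `"UNCLASSIFIED"`),
#'   `total_depth` and `qc_pass`.
#' @export
detect_nonmaternal <- function(counts, maternal, threshold = 0.01,
                               min_depth = 50L) {
  stopifnot(inherits(counts, "mh_counts"), inherits(maternal, "mh_genotype"))
  if (!identical(counts$locus_id, maternal$locus_id))
    stop("locus mismatch: counts at ", counts$locus_id,
         ", maternal genotype at ", maternal$locus_id)
  qc_pass <- counts$total_depth >= min_depth && counts$total_depth > 0L
  if (counts$total_depth > 0L) {
    ratios <- allele_ratios(counts)
  } else {
    ratios <- stats::setNames(numeric(0), character(0))
  }
  observed <- names(ratios)[ratios >= threshold]
  nm_alleles <- setdiff(observed, maternal$alleles)
  nonmaternal <- data.frame(
    allele = nm_alleles,
    depth = as.integer(counts$depth[nm_alleles]),
    ratio = unname(ratios[nm_alleles]),
    stringsAsFactors = FALSE
  )
  nonmaternal <- nonmaternal[order(-nonmaternal$depth, nonmaternal$allele), ,
                             drop = FALSE]
  rownames(nonmaternal) <- NULL
  n_nm <- nrow(nonmaternal)
  pattern <- if (!qc_pass || n_nm > 2L) "UNCLASSIFIED"
             else c("TYPE_I", "TYPE_II", "TYPE_III")[n_nm + 1L]
  structure(list(locus_id = counts$locus_id,
                 maternal_alleles = maternal$alleles,
                 observed_alleles = sort(observed),
                 nonmaternal = nonmaternal,
                 pattern_type = pattern,
                 total_depth = counts$total_depth,
                 qc_pass = qc_pass),
            class = "mh_locus_call")
}

#' @export
print.mh_locus_call <- function(x, ...) {
  cat(x$locus_id, ": ", x$pattern_type, ", D=", x$total_depth,
      ", nonmaternal: ",
      if (nrow(x$nonmaternal)) paste(x$nonmaternal$allele, collapse = ",")
      else "-", "\n", sep = "")
  invisible(x)
}

#' Call every locus of a plasma case against the maternal genotype
#'
#' Runs [detect_nonmaternal()] at each plasma locus for which the maternal
#' profile has a genotype; loci without a maternal genotype are skipped with
#' a warning.
#'
#' @param plasma An `mh_plasma` profile.
#' @param maternal_profile The mother's `mh_profile`.
#' @inheritParams detect_nonmaternal
#' @return An object of class `mh_case_calls` with fields `case_id`, `calls`
#'   (named list of `mh_locus_call`), `threshold`, `min_depth`.
#' @export
call_case <- function(plasma, maternal_profile, threshold = 0.01,
                      min_depth = 50L) {
  stopifnot(inherits(plasma, "mh_plasma"),
            inherits(maternal_profile, "mh_profile"))
  usable <- intersect(names(plasma$loci), names(maternal_profile$genotypes))
  if (length(usable) == 0L)
    stop("case ", plasma$case_id,
         ": no overlap between plasma loci and maternal genotypes")
  skipped <- setdiff(names(plasma$loci), usable)
  if (length(skipped))
    warning("case ", plasma$case_id, ": skipping ", length(skipped),
            " plasma locus/loci without maternal genotype: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  calls <- lapply(usable, function(loc) {
    detect_nonmaternal(plasma$loci[[loc]],
                       maternal_profile$genotypes[[loc]],
                       threshold = threshold, min_depth = min_depth)
  })
  names(calls) <- usable
  structure(list(case_id = plasma$case_id, calls = calls,
                 threshold = threshold, min_depth = min_depth),
            class = "mh_case_calls")
}

#' Summary counters for a called case
#'
#' Mirrors the per-case columns of the package's cohort reports: number of
#' loci with at least one assumed paternal allele, number of informative
#' (Type III) loci, and the total count of assumed paternal alleles.
#'
#' @param calls An `mh_case_calls` object.
#' @return Named list with `n_loci_pa`, `n_informative`, `n_assumed_pa`,
#'   `n_usable`, `n_unclassified`.
#' @export
case_summary <- function(calls) {
  stopifnot(inherits(calls, "mh_case_calls"))
  ok <- Filter(function(x) x$qc_pass && x$pattern_type != "UNCLASSIFIED",
               calls$calls)
  n_nm <- vapply(ok, function(x) nrow(x$nonmaternal), integer(1))
  list(n_loci_pa = sum(n_nm >= 1L),
       n_informative = sum(n_nm == 2L),
       n_assumed_pa = sum(n_nm),
       n_usable = length(ok),
       n_unclassified = length(calls$calls) - length(ok))
}

#' @export
print.mh_case_calls <- function(x, ...) {
  s <- case_summary(x)
  cat("Case ", x$case_id, ": ", length(x$calls), " loci called (threshold ",
      x$threshold, ", min depth ", x$min_depth, ")\n",
      "  loci with assumed PA: ", s$n_loci_pa,
      "; informative (Type III): ", s$n_informative,
      "; assumed PAs: ", s$n_assumed_pa, "\n", sep = "")
  invisible(x)
}
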