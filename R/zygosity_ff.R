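#' Call twin zygosity from informative loci
#'
#' A locus showing two distinct nonmaternal alleles (Type III) requires two
#' genetically distinct fetal contributors, so its presence is evidence of a
#' dizygotic (DZ) pregnancy. The call is DZ when the number of informative
#' loci reaches `min_informative` (default 1) and monozygotic (MZ)
#' otherwise.
#'
#' @param calls An `mh_case_calls` object, or an integer count of informative
#'   loci (useful for applying the rule to published per-case summaries).
#' @param min_informative Minimum number of Type III loci required for a DZ
#'   call. Default 1.
#' @param ... Unused.
#' @return An object of class `mh_zygosity` with fields `case_id`,
#'   `n_informative`, `call` (`"MZ"` or `"DZ"`), `informative_loci`,
#'   `min_informative`.
#' @export
call_zygosity <- function(calls, min_informative = 1L, ...) {
  UseMethod("call_zygosity")
}

#' @rdname call_zygosity
#' @export
call_zygosity.mh_case_calls <- function(calls, min_informative = 1L, ...) {
  usable <- Filter(function(x) x$qc_pass && x$pattern_type != "UNCLASSIFIED",
                   calls$calls)
  if (length(usable) == 0L)
    stop("case ", calls$case_id, ": no usable locus, zygosity cannot be called")
  inf_loci <- names(Filter(function(x) x$pattern_type == "TYPE_III", usable))
  new_zygosity(calls$case_id, length(inf_loci), inf_loci, min_informative)
}

#' @rdname call_zygosity
#' @param case_id Optional case label(s) when `calls` is a count vector.
#' @export
call_zygosity.numeric <- function(calls, min_informative = 1L,
                                  case_id = NULL, ...) {
  if (any(calls < 0) || any(calls != round(calls)))
    stop("informative-locus counts must be non-negative integers")
  if (is.null(case_id)) case_id <- as.character(seq_along(calls))
  out <- Map(function(n, id) new_zygosity(id, as.integer(n), character(0),
                                          min_informative),
             calls, case_id)
  if (length(out) == 1L) out[[1]] else out
}

new_zygosity <- function(case_id, n_informative, inf_loci, min_informative) {
  structure(list(case_id = as.character(case_id),
                 n_informative = as.integer(n_informative),
                 call = if (n_informative >= min_informative) "DZ" else "MZ",
                 informative_loci = inf_loci,
                 min_informative = as.integer(min_informative)),
            class = "mh_zygosity")
}

#' @export
print.mh_zygosity <- function(x, ...) {
  cat("Case ", x$case_id, ": ", x$call, " (", x$n_informative,
      " informative locus/loci, threshold ", x$min_informative, ")\n",
      sep = "")
  invisible(x)
}

#' Estimate per-fetus fetal fractions for a dizygotic case
#'
#' At each informative (Type III) locus the two fetus-specific alleles are
#' ordered by read depth; the lower-depth allele is attributed to the fetus
#' with the lower fetal fraction and the higher-depth allele to the other.
#' Writing d(l)_i and d(h)_i for those depths and D_i for total locus depth,
#' the estimates over the N informative loci are
#' \deqn{\bar{FF}(l) = \frac{1}{N}\sum_i 2 d(l)_i / D_i, \qquad
#'       \bar{FF}(h) = \frac{1}{N}\sum_i 2 d(h)_i / D_i,}
#' and the combined fetal fraction is their sum. The factor 2 reflects that a
#' fetus-specific allele carries one of the fetus's two genome copies. Loci
#' with a single nonmaternal allele (Type II) are excluded: a shared allele
#' cannot be attributed to one fetus.
#'
#' @param calls An `mh_case_calls` object with at least one Type III locus.
#' @return An object of class `mh_ff` with fields `case_id`, `ff_lower`,
#'   `ff_higher`, `ff_combined` (fractions), `n_loci_used`, `zygosity`
#'   (`"DZ"`), and `per_locus` (data.frame locus_id, d_lower, d_higher,
#'   total_depth, ff_lower_i, ff_higher_i).
#' @export
estimate_ff_dz <- function(calls) {
  stopifnot(inherits(calls, "mh_case_calls"))
  inf <- Filter(function(x) x$qc_pass && x$pattern_type == "TYPE_III",
                calls$calls)
  if (length(inf) == 0L)
    stop("case ", calls$case_id,
         ": no informative (Type III) locus; use estimate_ff_mz() for ",
         "monozygotic cases")
  per <- do.call(rbind, lapply(inf, function(x) {
    d <- sort(x$nonmaternal$depth)  # two alleles: lower, higher
    data.frame(locus_id = x$locus_id, d_lower = d[1], d_higher = d[2],
               total_depth = x$total_depth,
               ff_lower_i = 2 * d[1] / x$total_depth,
               ff_higher_i = 2 * d[2] / x$total_depth,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  ffl <- mean(per$ff_lower_i)
  ffh <- mean(per$ff_higher_i)
  structure(list(case_id = calls$case_id, ff_lower = ffl, ff_higher = ffh,
                 ff_combined = ffl + ffh, n_loci_used = nrow(per),
                 zygosity = "DZ", per_locus = per),
            class = "mh_ff")
}

#' Estimate the combined fetal fraction for a monozygotic case
#'
#' For genetically identical twins the plasma pattern is that of a singleton:
#' at each Type II locus the single fetus-specific allele carries half the
#' combined fetal contribution, so the combined fetal fraction is the mean of
#' 2 d_f_i / D_i over those loci. Per-fetus fractions are not identifiable
#' and are reported as `NA`.
#'
#' @param calls An `mh_case_calls` object with at least one Type II locus.
#' @return An `mh_ff` object with `ff_lower` and `ff_higher` set to `NA`.
#' @export
estimate_ff_mz <- function(calls) {
  stopifnot(inherits(calls, "mh_case_calls"))
  t2 <- Filter(function(x) x$qc_pass && x$pattern_type == "TYPE_II",
               calls$calls)
  if (length(t2) == 0L)
    stop("case ", calls$case_id, ": no Type II locus, combined FF undefined")
  per <- do.call(rbind, lapply(t2, function(x) {
    d <- x$nonmaternal$depth[1]
    data.frame(locus_id = x$locus_id, d_fetal = d,
               total_depth = x$total_depth,
               ff_i = 2 * d / x$total_depth, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(case_id = calls$case_id, ff_lower = NA_real_,
                 ff_higher = NA_real_, ff_combined = mean(per$ff_i),
                 n_loci_used = nrow(per), zygosity = "MZ", per_locus = per),
            class = "mh_ff")
}

#' Estimate fetal fraction according to a zygosity call
#'
#' Dispatches to [estimate_ff_dz()] or [estimate_ff_mz()].
#'
#' @param calls An `mh_case_calls` object.
#' @param zygosity An `mh_zygosity` object or `"MZ"`/`"DZ"`.
#' @return An `mh_ff` object.
#' @export
estimate_ff <- function(calls, zygosity) {
  z <- if (inherits(zygosity, "mh_zygosity")) zygosity$call else zygosity
  if (identical(z, "DZ")) estimate_ff_dz(calls) else estimate_ff_mz(calls)
}

#' @export
print.mh_ff <- function(x, ...) {
  cat("Case ", x$case_id, " (", x$zygosity, "): combined FF ",
      format_percent(x$ff_combined), "%",
      if (!is.na(x$ff_lower))
        paste0(" (lower ", format_percent(x$ff_lower), "%, higher ",
               format_percent(x$ff_higher), "%)"),
      " over ", x$n_loci_used, " loci\n", sep = "")
  invisible(x)
}

#' Ratio of higher to lower fetal fraction
#'
#' Quantifies how unequally the two fetuses of a dizygotic pair contribute
#' cfDNA to the maternal circulation.
#'
#' @param estimate An `mh_ff` object from a DZ case.
#' @return `ff_higher / ff_lower`.
#' @export
ff_ratio <- function(estimate) {
  stopifnot(inherits(estimate, "mh_ff"))
  if (is.na(estimate$ff_lower) || is.na(estimate$ff_higher))
    stop("per-fetus fetal fractions absent (monozygotic case?)")
  if (estimate$ff_lower == 0)
    stop("lower fetal fraction is zero, ratio undefined")
  estimate$ff_higher / estimate$ff_lower
}

#' Validate plasma calls against fetal reference genotypes
#'
#' With genotypes of both fetuses available (e.g. from amniocentesis), the
#' real fetus-specific allele set at each locus is the union of fetal alleles
#' absent from the maternal genotype. Assumed paternal alleles from the
#' plasma calls are then scored: dropouts are real alleles missed in plasma,
#' drop-ins are assumed alleles carried by neither fetus, and the detection
#' rate is (real - dropout) / real. Validated per-fetus fetal fractions are
#' recomputed at real informative loci using the true fetus-to-allele
#' assignment (plasma depth 0 for dropped-out alleles).
#'
#' @param calls An `mh_case_calls` object.
#' @param fetal1,fetal2 `mh_profile` objects for the two fetuses (pass the
#'   same profile twice for monozygotic twins).
#' @param maternal The mother's `mh_profile`.
#' @return An object of class `mh_validation`: `case_id`, `n_real_pa`,
#'   `n_dropout`, `n_dropin`, `detection_rate`, `n_loci_real_pa`,
#'   `n_real_informative`, validated fractions `ff_lower`, `ff_higher`,
#'   `ff_combined`, and `ratio_h_over_l` (`NA` for MZ).
#' @export
validate_against_fetal_genotypes <- function(calls, fetal1, fetal2, maternal) {
  stopifnot(inherits(calls, "mh_case_calls"), inherits(fetal1, "mh_profile"),
            inherits(fetal2, "mh_profile"), inherits(maternal, "mh_profile"))
  loci <- names(calls$calls)
  covered <- loci %in% names(fetal1$genotypes) &
    loci %in% names(fetal2$genotypes) & loci %in% names(maternal$genotypes)
  if (!all(covered))
    stop("fetal/maternal reference genotypes missing at locus/loci: ",
         paste(utils::head(loci[!covered], 5), collapse = ", "))
  n_real <- 0L; n_drop <- 0L; n_dropin <- 0L
  n_loci_real <- 0L; n_real_inf <- 0L
  ff1 <- c(); ff2 <- c(); ff_single <- c()
  for (loc in loci) {
    call <- calls$calls[[loc]]
    mat <- maternal$genotypes[[loc]]$alleles
    pa1 <- setdiff(fetal1$genotypes[[loc]]$alleles, mat)
    pa2 <- setdiff(fetal2$genotypes[[loc]]$alleles, mat)
    real <- union(pa1, pa2)
    detected <- call$nonmaternal$allele
    n_real <- n_real + length(real)
    n_drop <- n_drop + length(setdiff(real, detected))
    n_dropin <- n_dropin + length(setdiff(detected, real))
    n_loci_real <- n_loci_real + (length(real) >= 1L)
    depth_of <- function(a) {
      i <- match(a, call$nonmaternal$allele)
      if (is.na(i)) 0L else call$nonmaternal$depth[i]
    }
    if (length(real) == 2L) {
      n_real_inf <- n_real_inf + 1L
      ff1 <- c(ff1, 2 * depth_of(pa1) / call$total_depth)
      ff2 <- c(ff2, 2 * depth_of(pa2) / call$total_depth)
    } else if (length(real) == 1L && setequal(pa1, pa2)) {
      # allele shared by both fetuses: contributes to a combined estimate
      ff_single <- c(ff_single, 2 * depth_of(real) / call$total_depth)
    }
  }
  if (n_real == 0L)
    stop("case ", calls$case_id, ": no real fetus-specific allele to validate")
  if (n_real_inf > 0L) {
    m1 <- mean(ff1); m2 <- mean(ff2)
    ffl <- min(m1, m2); ffh <- max(m1, m2)
    ffc <- ffl + ffh
    ratio <- if (ffl > 0) ffh / ffl else NA_real_
  } else {
    ffl <- NA_real_; ffh <- NA_real_
    ffc <- if (length(ff_single)) mean(ff_single) else NA_real_
    ratio <- NA_real_
  }
  structure(list(case_id = calls$case_id, n_real_pa = n_real,
                 n_dropout = n_drop, n_dropin = n_dropin,
                 detection_rate = (n_real - n_drop) / n_real,
                 n_loci_real_pa = n_loci_real,
                 n_real_informative = n_real_inf,
                 ff_lower = ffl, ff_higher = ffh, ff_combined = ffc,
                 ratio_h_over_l = ratio),
            class = "mh_validation")
}

#' @export
print.mh_validation <- function(x, ...) {
  cat("Case ", x$case_id, ": ", x$n_real_pa, " real PAs, ", x$n_dropout,
      " dropout, ", x$n_dropin, " drop-in; detection rate ",
      format_percent(x$detection_rate), "%\n", sep = "")
  invisible(x)
}

#' Concordance of estimated vs validated fetal fractions
#'
#' Squared Pearson correlation between estimated and validated fetal
#' fractions across dizygotic cases (equal to the coefficient of
#' determination of the least-squares line through the scatter).
#'
#' @param estimates,validated Data frames paired by `case_id`, each with
#'   numeric columns `ff_lower`, `ff_higher`, `ff_combined` (units must
#'   match between the two; MZ rows with `NA` per-fetus values are dropped).
#' @return Named numeric vector `c(r2_lower, r2_higher, r2_combined)`.
#' @export
ff_concordance <- function(estimates, validated) {
  stopifnot(is.data.frame(estimates), is.data.frame(validated))
  need <- c("case_id", "ff_lower", "ff_higher", "ff_combined")
  if (!all(need %in% names(estimates)) || !all(need %in% names(validated)))
    stop("both inputs need columns: ", paste(need, collapse = ", "))
  m <- merge(estimates[need], validated[need], by = "case_id",
             suffixes = c("_est", "_val"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L)
    stop("at least 3 paired dizygotic cases required, got ", nrow(m))
  r2 <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero variance: R^2 undefined")
    stats::cor(a, b)^2
  }
  c(r2_lower = r2(m$ff_lower_est, m$ff_lower_val),
    r2_higher = r2(m$ff_higher_est, m$ff_higher_val),
    r2_combined = r2(m$ff_combined_est, m$ff_combined_val))
}
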