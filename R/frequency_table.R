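#' Microhaplotype allele-frequency table
#'
#' A frequency table maps each panel locus to population frequencies of its
#' haplotype alleles. Every probability computation in the package (genotype
#' priors, drop-in weights, random-man allele draws) reads from one of these.
#' Alleles absent from a locus never have frequency zero: lookups fall back to
#' `unseen_freq`, a small floor applied to alleles not present in the
#' reference data set.
#'
#' @param entries Named list: one element per locus, each a named numeric
#'   vector of allele frequencies (names are haplotype allele strings).
#' @param unseen_freq Frequency assigned to alleles absent from a locus.
#'   Default 0.002.
#' @return An object of class `mh_freqs`.
#' @export
frequency_table <- function(entries, unseen_freq = 0.002) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  if (is.null(names(entries)) || anyNA(names(entries)) || any(names(entries) == ""))
    stop("every locus in a frequency table must be named")
  if (!is.numeric(unseen_freq) || length(unseen_freq) != 1L ||
      unseen_freq <= 0 || unseen_freq >= 1)
    stop("unseen_freq must be a single frequency in (0, 1)")
  for (loc in names(entries)) {
    p <- entries[[loc]]
    if (!is.numeric(p) || is.null(names(p)) || any(names(p) == ""))
      stop("locus ", loc, ": frequencies must be a named numeric vector")
    if (anyDuplicated(names(p)))
      stop("locus ", loc, ": duplicated allele labels")
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop("locus ", loc, ": frequencies must lie in (0, 1]")
    if (sum(p) > 1 + 1e-6)
      stop("locus ", loc, ": allele frequencies sum to ", format(sum(p)),
           " (> 1 + 1e-6)")
  }
  structure(list(entries = entries, unseen_freq = unseen_freq),
            class = "mh_freqs")
}

#' Read a frequency table from TSV
#'
#' Expects a tab-delimited file with header columns `locus`, `allele`,
#' `frequency`.
#'
#' @param path Path to the TSV file.
#' @inheritParams frequency_table
#' @return An `mh_freqs` object.
#' @export
read_frequency_table <- function(path, unseen_freq = 0.002) {
  df <- read_tsv_checked(path, c("locus", "allele", "frequency"))
  if (!is.numeric(df$frequency))
    stop("column 'frequency' must be numeric")
  if (anyDuplicated(df[c("locus", "allele")]))
    stop("duplicated (locus, allele) rows in ", path)
  entries <- lapply(split(df, df$locus), function(g) {
    stats::setNames(g$frequency, as.character(g$allele))
  })
  frequency_table(entries, unseen_freq = unseen_freq)
}

#' Write a frequency table to TSV
#'
#' @param freqs An `mh_freqs` object.
#' @param path Output path.
#' @export
write_frequency_table <- function(freqs, path) {
  stopifnot(inherits(freqs, "mh_freqs"))
  rows <- lapply(names(freqs$entries), function(loc) {
    p <- freqs$entries[[loc]]
    data.frame(locus = loc, allele = names(p), frequency = unname(p),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up an allele frequency with the unseen-allele floor
#'
#' Returns the tabulated frequency when the allele is present at the locus
#' and `unseen_freq` otherwise; never zero.
#'
#' @param freqs An `mh_freqs` object.
#' @param locus Locus id.
#' @param allele Character vector of allele labels.
#' @return Numeric vector of frequencies.
#' @export
allele_freq <- function(freqs, locus, allele) {
  stopifnot(inherits(freqs, "mh_freqs"))
  p <- freqs$entries[[locus]]
  out <- unname(p[allele])
  out[is.na(out)] <- freqs$unseen_freq
  out
}

#' Panel locus ids of a frequency table
#' @param freqs An `mh_freqs` object.
#' @return Character vector of locus ids.
#' @export
panel_loci <- function(freqs) {
  stopifnot(inherits(freqs, "mh_freqs"))
  names(freqs$entries)
}

#' Effective number of alleles per locus
#'
#' Ae = 1 / sum(p^2), a standard measure of locus polymorphism and
#' mixture-resolving power.
#'
#' @param freqs An `mh_freqs` object.
#' @return Named numeric vector, one Ae per locus.
#' @export
effective_alleles <- function(freqs) {
  stopifnot(inherits(freqs, "mh_freqs"))
  vapply(freqs$entries, function(p) 1 / sum((p / sum(p))^2), numeric(1))
}

#' @export
print.mh_freqs <- function(x, ...) {
  cat("Microhaplotype frequency table:", length(x$entries), "loci,",
      "unseen-allele floor", x$unseen_freq, "\n")
  invisible(x)
}

# Shared TSV reader: enforces header presence and returns a data.frame with
# character columns except where the caller coerces.
read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}
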