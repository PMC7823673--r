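#' Per-locus plasma read counts
#'
#' Read depths per observed allele at one locus of a maternal plasma cfDNA
#' sample. The total depth D is the sum over alleles; alleles with zero depth
#' are omitted.
#'
#' @param locus Locus id.
#' @param depth Named integer vector of per-allele read counts.
#' @return An object of class `mh_counts` with fields `locus_id`, `depth`,
#'   `total_depth`.
#' @export
plasma_counts <- function(locus, depth) {
  if (length(depth) && (is.null(names(depth)) || any(!nzchar(names(depth)))))
    stop("locus ", locus, ": depths must be named by allele")
  if (anyDuplicated(names(depth)))
    stop("locus ", locus, ": duplicated allele in depth map")
  if (any(depth < 0)) stop("locus ", locus, ": negative read depth")
  if (any(depth != round(depth))) stop("locus ", locus, ": non-integer read depth")
  depth <- depth[depth > 0]
  structure(list(locus_id = as.character(locus),
                 depth = depth,
                 total_depth = as.integer(sum(depth))),
            class = "mh_counts")
}

#' Plasma read-count profile of one case
#'
#' @param case_id Case identifier.
#' @param loci List of `mh_counts`, one per locus.
#' @return An object of class `mh_plasma`.
#' @export
plasma_profile <- function(case_id, loci) {
  stopifnot(is.character(case_id), length(case_id) == 1L)
  ids <- vapply(loci, function(x) x$locus_id, character(1))
  if (anyDuplicated(ids)) stop("case ", case_id, ": duplicated locus")
  names(loci) <- ids
  structure(list(case_id = case_id, loci = loci), class = "mh_plasma")
}

#' @export
print.mh_plasma <- function(x, ...) {
  cat("Plasma profile", x$case_id, "-", length(x$loci), "loci, median depth",
      if (length(x$loci))
        stats::median(vapply(x$loci, `[[`, integer(1), "total_depth"))
      else NA, "\n")
  invisible(x)
}

#' Read plasma count profiles from TSV
#'
#' Expects columns `case`, `locus`, `allele`, `depth` (non-negative
#' integers). Zero-depth rows are dropped. `read_plasma_profiles()` returns
#' every case in the file; `read_plasma_profile()` a single one.
#'
#' @param path Path to the TSV file.
#' @return Named list of `mh_plasma` objects.
#' @export
read_plasma_profiles <- function(path) {
  df <- read_tsv_checked(path, c("case", "locus", "allele", "depth"))
  if (nrow(df) == 0L) {
    warning("empty plasma count file: ", path)
    return(list())
  }
  if (!is.numeric(df$depth)) stop("column 'depth' must be numeric")
  if (any(df$depth < 0)) stop("negative read depth in ", path)
  if (any(df$depth != round(df$depth))) stop("non-integer read depth in ", path)
  df$case <- as.character(df$case)
  df$locus <- as.character(df$locus)
  df$allele <- as.character(df$allele)
  out <- lapply(split(df, df$case), function(g) {
    loci <- lapply(split(g, g$locus), function(h) {
      plasma_counts(h$locus[1], stats::setNames(as.integer(h$depth), h$allele))
    })
    plasma_profile(g$case[1], unname(loci))
  })
  out[order(names(out))]
}

#' @rdname read_plasma_profiles
#' @param case Case id to extract; may be omitted when the file holds one case.
#' @export
read_plasma_profile <- function(path, case = NULL) {
  profs <- read_plasma_profiles(path)
  if (length(profs) == 0L)
    return(plasma_profile(if (is.null(case)) "empty" else case, list()))
  if (is.null(case)) {
    if (length(profs) != 1L)
      stop(path, " holds ", length(profs), " cases; specify which one to read")
    return(profs[[1]])
  }
  if (!case %in% names(profs)) stop("case ", case, " not found in ", path)
  profs[[case]]
}

#' Write plasma count profiles to TSV
#'
#' @param profiles A single `mh_plasma` or a list of them.
#' @param path Output path.
#' @export
write_plasma_profiles <- function(profiles, path) {
  if (inherits(profiles, "mh_plasma")) profiles <- list(profiles)
  rows <- lapply(profiles, function(pr) {
    do.call(rbind, lapply(pr$loci, function(lc) {
      data.frame(case = pr$case_id, locus = lc$locus_id,
                 allele = names(lc$depth), depth = unname(lc$depth),
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(case = character(), locus = character(),
                     allele = character(), depth = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
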