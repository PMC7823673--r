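#' Diploid genotype at a microhaplotype locus
#'
#' An unordered pair of haplotype allele strings; the two slots may be equal
#' (homozygote). Comparison is order-independent: the alleles are stored
#' sorted.
#'
#' @param locus Locus id.
#' @param a1,a2 Allele strings.
#' @return An object of class `mh_genotype` with fields `locus_id` and
#'   `alleles` (sorted character vector of length 2).
#' @export
genotype <- function(locus, a1, a2) {
  if (!nzchar(a1) || !nzchar(a2) || is.na(a1) || is.na(a2))
    stop("locus ", locus, ": empty allele in genotype")
  structure(list(locus_id = as.character(locus),
                 alleles = sort(c(as.character(a1), as.character(a2)))),
            class = "mh_genotype")
}

#' @export
print.mh_genotype <- function(x, ...) {
  cat(x$locus_id, ": {", paste(x$alleles, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Test genotype equality (order-independent)
#' @param e1,e2 `mh_genotype` objects.
#' @export
`==.mh_genotype` <- function(e1, e2) {
  identical(e1$locus_id, e2$locus_id) && identical(e1$alleles, e2$alleles)
}

#' Genotype profile of one individual
#'
#' @param sample_id Sample name.
#' @param genotypes List of `mh_genotype` objects, at most one per locus.
#' @return An object of class `mh_profile`.
#' @export
genotype_profile <- function(sample_id, genotypes) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  loci <- vapply(genotypes, function(g) g$locus_id, character(1))
  if (anyDuplicated(loci))
    stop("sample ", sample_id, ": more than one genotype at locus ",
         loci[duplicated(loci)][1])
  names(genotypes) <- loci
  structure(list(sample_id = sample_id, genotypes = genotypes),
            class = "mh_profile")
}

#' @export
print.mh_profile <- function(x, ...) {
  cat("Genotype profile", x$sample_id, "-", length(x$genotypes), "loci\n")
  invisible(x)
}

#' Read genotype profiles from TSV
#'
#' Expects columns `sample`, `locus`, `allele1`, `allele2`. One file may hold
#' several individuals; `read_genotype_profiles()` returns all of them,
#' `read_genotype_profile()` returns a single one.
#'
#' @param path Path to the TSV file.
#' @return Named list of `mh_profile` objects, one per sample.
#' @export
read_genotype_profiles <- function(path) {
  df <- read_tsv_checked(path, c("sample", "locus", "allele1", "allele2"))
  df$sample <- as.character(df$sample)
  df$locus <- as.character(df$locus)
  df$allele1 <- as.character(df$allele1)
  df$allele2 <- as.character(df$allele2)
  if (any(!nzchar(df$allele1)) || any(!nzchar(df$allele2)) ||
      anyNA(df$allele1) || anyNA(df$allele2))
    stop("empty allele field in ", path)
  out <- lapply(split(df, df$sample), function(g) {
    gts <- Map(genotype, g$locus, g$allele1, g$allele2)
    genotype_profile(g$sample[1], unname(gts))
  })
  out[order(names(out))]
}

#' @rdname read_genotype_profiles
#' @param sample Sample id to extract; may be omitted when the file holds a
#'   single individual.
#' @return For `read_genotype_profile()`, a single `mh_profile`.
#' @export
read_genotype_profile <- function(path, sample = NULL) {
  profs <- read_genotype_profiles(path)
  if (is.null(sample)) {
    if (length(profs) != 1L)
      stop(path, " holds ", length(profs),
           " samples; specify which one to read")
    return(profs[[1]])
  }
  if (!sample %in% names(profs))
    stop("sample ", sample, " not found in ", path)
  profs[[sample]]
}

#' Write genotype profiles to TSV
#'
#' @param profiles A single `mh_profile` or a list of them.
#' @param path Output path.
#' @export
write_genotype_profiles <- function(profiles, path) {
  if (inherits(profiles, "mh_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(pr) {
    data.frame(sample = pr$sample_id,
               locus = vapply(pr$genotypes, `[[`, character(1), "locus_id"),
               allele1 = vapply(pr$genotypes, function(g) g$alleles[1], character(1)),
               allele2 = vapply(pr$genotypes, function(g) g$alleles[2], character(1)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
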