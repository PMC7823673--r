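#' Write a result table or record to disk
#'
#' TSV output renders fetal-fraction and rate columns as percentages with two
#' decimals and log10 likelihood-ratio columns with three decimals, the
#' conventions used throughout the package's reports. Column order is kept as
#' given, so identical inputs produce byte-identical files. JSON output
#' preserves full numeric precision and round-trips through
#' [read_report()].
#'
#' @param results A data.frame (TSV or JSON) or a list record (JSON only).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
    return(invisible(path))
  }
  if (!is.data.frame(results))
    stop("TSV reports require a data.frame")
  out <- results
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    if (grepl("log10", nm, ignore.case = TRUE)) {
      out[[nm]] <- format_fixed(out[[nm]], 3)
    } else if (grepl("(^|_)ff($|_)|(^|_)rate($|_)|fraction", nm, ignore.case = TRUE)) {
      out[[nm]] <- format_percent(out[[nm]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return The parsed record (data.frames are restored as data.frames).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render a fraction as a percentage string with two decimals
#'
#' Uses round-half-to-even at two decimals on the percent scale, e.g.
#' 0.0521 -> "5.21".
#'
#' @param x Numeric vector of fractions in `[0, 1]` (NA allowed).
#' @return Character vector.
#' @export
format_percent <- function(x) {
  format_fixed(100 * x, 2)
}

format_fixed <- function(x, digits) {
  out <- ifelse(is.na(x), NA_character_,
                formatC(round(x, digits), format = "f", digits = digits))
  out
}
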