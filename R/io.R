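# Delimited-text I/O for peak tables, compound databases and reports.

#' Write / read a peak-feature table
#'
#' Tab-separated with columns `sample_id`, `mz`, `rt`, `area`, `intensity`,
#' `iso1`, `iso2`, `fragments` (semicolon-joined fragment m/z).
#'
#' @param features Peak table data frame.
#' @param path File path.
#' @export
write_peak_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  f <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(fragments = "character"))
  .validate_peak_table(f)
}

#' Write / read a compound database
#'
#' @param db Compound database data frame (see [target_screen()]).
#' @param path File path.
#' @export
write_compound_db <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_db
#' @export
read_compound_db <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(fragments = "character"),
                    check.names = FALSE)
}

#' Write a report table with a stamped header
#'
#' Tab-separated values preceded by `#`-prefixed header lines recording the
#' configuration hash and seed, so every artifact of a run is traceable.
#'
#' @param x Data frame.
#' @param path File path.
#' @param header Named character vector of header fields.
#' @export
write_report <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
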