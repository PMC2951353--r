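#' Write a result table as TSV or JSON with a provenance header
#'
#' Output is bit-stable for identical input: column order is taken from
#' the data frame, floating-point columns are printed at a fixed
#' precision, and the provenance block contains only the values passed
#' in (no timestamps).  TSV files carry the provenance as `#`-prefixed
#' comment lines above the header; JSON files carry it as a `provenance`
#' object beside the `rows` array.
#'
#' @param records A data frame of homogeneous result rows (may have zero
#'   rows, in which case a header-only table is written).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param provenance Optional named list recorded verbatim in the header
#'   (inputs, parameters, seed, package version, ...).
#' @param digits Number of significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "json"),
                         provenance = NULL, digits = 6L) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  df <- records
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- signif(df[[j]], digits)
    }
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "tsv") {
    if (!is.null(provenance)) {
      for (k in names(provenance)) {
        writeLines(sprintf("# %s: %s", k,
                           paste(format(provenance[[k]]), collapse = " ")),
                   con)
      }
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
  } else {
    obj <- list(provenance = provenance, rows = df)
    if (is.null(provenance)) obj$provenance <- NULL
    writeLines(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null",
                                pretty = TRUE), con)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return A list with elements `provenance` (or `NULL`) and `rows`
#'   (a data frame).
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$rows)) obj$rows <- data.frame()
  obj
}

# Standard provenance block shared by the pipeline drivers.
provenance_block <- function(inputs = list(), params = list(), seed = NULL) {
  c(list(tool = "igtls",
         version = as.character(utils::packageVersion("igtls"))),
    inputs,
    params,
    if (!is.null(seed)) list(seed = seed))
}
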