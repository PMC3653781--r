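# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a plain tab-separated table
#'
#' Reads a TSV written by the package's writers: a header row, optional
#' leading `#` comment lines, no quoting.
#'
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_tsv_plain <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a plain tab-separated table
#'
#' Numeric (double) columns are rounded to 6 decimal places so that
#' write/read round-trips are exact at the documented precision. Coordinates
#' follow the 0-based half-open convention throughout the package; an
#' optional comment line can record that and other provenance.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with a
#'   leading `# `).
#' @return Invisibly, `path`.
#' @export
write_tsv_plain <- function(df, path, comment = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- round(out[[j]], 6)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
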