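# Probe-level array profile and promoter annotation I/O.
#
# Coordinates are 0-based half-open everywhere in the package; BED writers
# follow the BED convention and TSV writers state it in a header comment.

PROFILE_COLUMNS <- c("probe_id", "chrom", "start", "end", "log2_ratio")
ANNOTATION_COLUMNS <- c("gene_symbol", "accession", "chrom", "tss",
                        "strand", "start", "end")

as_array_profile <- function(df, condition_label) {
  condition_label <- match.arg(condition_label, c("Nor", "PV"))
  assert_columns(df, c("probe_id", "chrom", "start", "end", "value"),
                 "array profile")
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "condition") <- condition_label
  class(df) <- c("array_profile", "data.frame")
  df
}

#' Read a probe-level array profile
#'
#' Expects a TSV with columns `probe_id`, `chrom`, `start`, `end`,
#' `log2_ratio` (the scaled log2(IP/Input) value; a `value` column is also
#' accepted). Rows with a non-finite value are dropped with a warning;
#' malformed coordinates or duplicated probe identifiers are hard errors that
#' name the offending probe.
#'
#' @param path Path to the TSV.
#' @param condition_label "Nor" or "PV".
#' @return An `array_profile` data frame sorted by (chrom, start) with the
#'   measurement in column `value`.
#' @export
read_profile <- function(path, condition_label) {
  df <- read_tsv_plain(path)
  if ("log2_ratio" %in% names(df) && !"value" %in% names(df)) {
    names(df)[names(df) == "log2_ratio"] <- "value"
  }
  assert_columns(df, c("probe_id", "chrom", "start", "end", "value"),
                 sprintf("profile '%s'", path))
  df$start <- suppressWarnings(as.numeric(df$start))
  df$end <- suppressWarnings(as.numeric(df$end))
  bad_coord <- !is.finite(df$start) | !is.finite(df$end) | df$start < 0
  if (any(bad_coord)) {
    stop(sprintf("unparseable or negative coordinates for probe(s): %s",
                 paste(utils::head(df$probe_id[bad_coord], 5), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) {
    dup <- unique(df$probe_id[duplicated(df$probe_id)])
    stop(sprintf("duplicated probe_id(s): %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  rev_coord <- df$start >= df$end
  if (any(rev_coord)) {
    stop(sprintf("start >= end for probe(s): %s",
                 paste(utils::head(df$probe_id[rev_coord], 5), collapse = ", ")),
         call. = FALSE)
  }
  df$value <- suppressWarnings(as.numeric(df$value))
  drop <- !is.finite(df$value)
  if (any(drop)) {
    warning(sprintf("dropped %d probe(s) with non-finite values", sum(drop)),
            call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  as_array_profile(df[, c("probe_id", "chrom", "start", "end", "value")],
                   condition_label)
}

#' Write a probe-level array profile
#'
#' @param profile An `array_profile`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(
    probe_id = profile$probe_id, chrom = profile$chrom,
    start = profile$start, end = profile$end,
    log2_ratio = profile$value, stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path, comment = c(
    "coordinates: 0-based half-open",
    sprintf("condition: %s", attr(profile, "condition") %||% "NA"),
    sprintf("normalization: %s", attr(profile, "normalization") %||% "none")
  ))
}

#' Tukey biweight location estimate
#'
#' Iteratively reweighted one-dimensional location M-estimate with the
#' biweight function, the scaling used for NimbleGen log2-ratio data. Scale
#' is fixed at the MAD of the input; falls back to the median when the MAD
#' is zero or all weights vanish.
#'
#' @param x Numeric vector (finite values).
#' @param c_tuning Tuning constant in MAD units (default 5).
#' @param eps Relative convergence tolerance on the location update; the
#'   default iterates essentially to machine precision so that centering is
#'   idempotent and shift-invariant to well below 1e-12.
#' @param max_iter Iteration cap.
#' @return The location estimate (scalar).
#' @export
tukey_biweight <- function(x, c_tuning = 5, eps = 1e-15, max_iter = 200) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  t0 <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) return(t0)
  for (i in seq_len(max_iter)) {
    u <- (x - t0) / (c_tuning * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (sum(w) == 0) return(stats::median(x))
    t1 <- sum(w * x) / sum(w)
    if (t1 == t0 || abs(t1 - t0) <= eps * max(1, abs(t0))) return(t1)
    t0 <- t1
  }
  t0
}

#' Normalize (center) an array profile
#'
#' Centers the log2-ratio values so that a robust location estimate is zero:
#' the Tukey biweight mean by default, the median, or no centering. The
#' original object is left unmodified; the method and subtracted center are
#' recorded as provenance attributes. Centering is idempotent and
#' shift-invariant; note the downstream rank-based KS peak caller is itself
#' invariant to any global shift, so centering only affects the
#' interpretability of reported log-ratios.
#'
#' @param profile An `array_profile` with at least 2 probes.
#' @param method "biweight" (default), "median" or "none".
#' @return The centered `array_profile`.
#' @export
normalize_profile <- function(profile, method = c("biweight", "median", "none")) {
  method <- match.arg(method)
  if (nrow(profile) < 2L) {
    stop("normalization needs at least 2 probes", call. = FALSE)
  }
  if (length(unique(profile$value)) == 1L && method != "none") {
    warning("degenerate all-equal profile; centered to all-zero", call. = FALSE)
  }
  center <- switch(method,
    biweight = tukey_biweight(profile$value),
    median = stats::median(profile$value),
    none = 0
  )
  out <- profile
  out$value <- out$value - center
  attr(out, "normalization") <- method
  attr(out, "normalization_center") <- center
  out
}

#' Read a promoter annotation table
#'
#' TSV with columns `gene_symbol`, `accession`, `chrom`, `tss`, `strand`,
#' `start`, `end` (0-based half-open, promoter window oriented by strand).
#'
#' @param path Path to the TSV.
#' @return The annotation data frame.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_plain(path)
  if (nrow(df) == 0L) {
    warning(sprintf("empty annotation: %s", path), call. = FALSE)
    empty <- data.frame(gene_symbol = character(), accession = character(),
                        chrom = character(), tss = integer(),
                        strand = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    return(empty)
  }
  assert_columns(df, ANNOTATION_COLUMNS, sprintf("annotation '%s'", path))
  if (!all(df$strand %in% c("+", "-"))) {
    stop("malformed strand (must be '+' or '-')", call. = FALSE)
  }
  for (col in c("tss", "start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("negative or unparseable '%s' coordinates", col),
           call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  if (anyDuplicated(df$accession)) {
    stop("accessions must be unique", call. = FALSE)
  }
  df[, ANNOTATION_COLUMNS]
}

#' Write a promoter annotation table
#'
#' @param annotation Annotation data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_plain(annotation[, ANNOTATION_COLUMNS],
                  path, comment = "coordinates: 0-based half-open")
}

#' Write intervals as BED6
#'
#' Emits a 6-column BED file (0-based half-open). The BED score column is
#' the peakscore scaled by 100 and capped at 1000 per BED convention; the
#' unrounded peakscore belongs in the TSV outputs.
#'
#' @param x Data frame with `chrom`, `start`, `end`; optionally a name
#'   column (`accession` or `name`), a `peakscore`/`score` column and a
#'   `strand` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  name <- x$name %||% x$accession %||% sprintf("feature%05d", seq_len(nrow(x)))
  score <- x$peakscore %||% x$score %||% rep(0, nrow(x))
  bed <- data.frame(
    chrom = x$chrom,
    start = x$start,
    end = x$end,
    name = name,
    score = pmin(as.integer(round(100 * score)), 1000L),
    strand = x$strand %||% rep(".", nrow(x)),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
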