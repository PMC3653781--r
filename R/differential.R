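# Two-condition peakscore classification of promoters.
#
# A promoter's peakscore per condition is the best peakscore among peaks
# overlapping its window (0 when none). A promoter is TE-specific
# hypomethylated when its peak is present in the post-vasectomy profile
# (score strictly above present_min) and absent in the normozoospermic
# profile (score strictly below absent_max); hypermethylated is the mirror
# image. Scores in [absent_max, present_min] are indeterminate by design.

#' Classification thresholds for TE-specific promoters
#'
#' Defaults follow the study's criteria: peakscore more than 3.0 (p < 0.001)
#' in the "present" condition and less than 2.0 (p > 0.01) in the "absent"
#' condition; both inequalities strict.
#'
#' @param present_min Minimum (exclusive) peakscore in the present condition.
#' @param absent_max Maximum (exclusive) peakscore in the absent condition.
#' @return An object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(present_min = 3, absent_max = 2) {
  assert_scalar_number(present_min, "present_min", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(absent_max, "absent_max", lower = 0,
                       strict_lower = TRUE)
  if (present_min <= absent_max) {
    stop("present_min must exceed absent_max", call. = FALSE)
  }
  structure(list(present_min = present_min, absent_max = absent_max),
            class = "classification_thresholds")
}

#' Assign condition-wise peakscores to promoters
#'
#' A peak is assigned to a promoter iff their intervals overlap by at least
#' 1 bp; a promoter's score per condition is the maximum peakscore over
#' assigned peaks, 0 if none. Every annotated promoter appears in the
#' output. Peaks on chromosomes absent from the annotation are ignored with
#' a warning.
#'
#' @param peaks_nor,peaks_pv Peak tables from [call_peaks()] for the Nor and
#'   PV profiles (either may be empty or NULL).
#' @param annotation Promoter annotation data frame.
#' @return Data frame with `accession`, `gene_symbol`, `peakscore_nor`,
#'   `peakscore_pv`.
#' @export
assign_promoter_scores <- function(peaks_nor, peaks_pv, annotation) {
  assert_columns(annotation, c("accession", "gene_symbol", "chrom",
                               "start", "end"), "annotation")
  prom_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end)
  )
  score_one <- function(peaks) {
    s <- numeric(nrow(annotation))
    if (is.null(peaks) || nrow(peaks) == 0L) return(s)
    unknown <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
    if (length(unknown)) {
      warning(sprintf("ignoring peaks on chromosome(s) absent from annotation: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
      peaks <- peaks[!peaks$chrom %in% unknown, , drop = FALSE]
      if (nrow(peaks) == 0L) return(s)
    }
    pk_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(pk_gr, prom_gr))
    if (length(hits)) {
      best <- tapply(peaks$peakscore[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits), max)
      s[as.integer(names(best))] <- as.numeric(best)
    }
    s
  }
  data.frame(
    accession = annotation$accession,
    gene_symbol = annotation$gene_symbol,
    peakscore_nor = score_one(peaks_nor),
    peakscore_pv = score_one(peaks_pv),
    stringsAsFactors = FALSE
  )
}

#' Classify promoters as TE-specific hypo-/hypermethylated
#'
#' Applies the two-condition peakscore criteria with strict inequalities:
#' hypomethylated iff `peakscore_pv > present_min` and
#' `peakscore_nor < absent_max`; hypermethylated iff the mirror holds;
#' everything else unclassified. An absent peak counts as score 0, so a
#' vasectomy-abolished signal satisfies the "absent" condition. Also flags
#' `identified`: promoters overlapped by at least one called peak in either
#' condition (nonzero score), the denominator used for identified-promoter
#' rates.
#'
#' @param scores Output of [assign_promoter_scores()].
#' @param thresholds A [classification_thresholds()].
#' @return The input with added columns `klass`
#'   ("te_hypomethylated"/"te_hypermethylated"/"unclassified") and
#'   `identified` (logical).
#' @export
classify_promoters <- function(scores, thresholds = classification_thresholds()) {
  assert_columns(scores, c("accession", "gene_symbol",
                           "peakscore_nor", "peakscore_pv"), "scores")
  stopifnot(all(scores$peakscore_nor >= 0), all(scores$peakscore_pv >= 0))
  hypo <- scores$peakscore_pv > thresholds$present_min &
    scores$peakscore_nor < thresholds$absent_max
  hyper <- scores$peakscore_nor > thresholds$present_min &
    scores$peakscore_pv < thresholds$absent_max
  out <- scores
  out$klass <- ifelse(hypo, "te_hypomethylated",
                      ifelse(hyper, "te_hypermethylated", "unclassified"))
  out$identified <- scores$peakscore_nor > 0 | scores$peakscore_pv > 0
  out
}

#' Summarize promoter calls to genes
#'
#' A gene with multiple promoters takes the unique differential class among
#' them if exactly one occurs; promoters carrying both differential classes
#' neutralize each other (`conflict_flag`, class unclassified); genes with
#' only unclassified promoters stay unclassified.
#'
#' @param promoter_calls Output of [classify_promoters()].
#' @return Data frame with `gene_symbol`, `klass`, `supporting_accessions`
#'   (comma-separated), `conflict_flag`.
#' @export
summarize_genes <- function(promoter_calls) {
  assert_columns(promoter_calls, c("gene_symbol", "accession", "klass"),
                 "promoter_calls")
  per_gene <- split(seq_len(nrow(promoter_calls)), promoter_calls$gene_symbol)
  rows <- lapply(names(per_gene), function(g) {
    i <- per_gene[[g]]
    kl <- promoter_calls$klass[i]
    diff_classes <- unique(kl[kl != "unclassified"])
    if (length(diff_classes) == 1L) {
      klass <- diff_classes
      conflict <- FALSE
      support <- promoter_calls$accession[i][kl == klass]
    } else {
      klass <- "unclassified"
      conflict <- length(diff_classes) > 1L
      support <- character()
    }
    data.frame(gene_symbol = g, klass = klass,
               supporting_accessions = paste(support, collapse = ","),
               conflict_flag = conflict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate class proportions and peakscore distributions
#'
#' Reports the percentage of promoters in each differential class and a
#' histogram of the "present"-condition peakscore per class (PV for
#' hypomethylated, Nor for hypermethylated) on half-open bins built from
#' `bin_edges` with an open-ended final bin. The percentage denominator is
#' either every scored promoter (`"all"`, the default, comparable to planted
#' class proportions) or only identified promoters (`"identified"`: overlap
#' with at least one called peak in either condition, the array study's
#' peak-bearing denominator); both counts are returned.
#'
#' @param promoter_calls Output of [classify_promoters()].
#' @param bin_edges Increasing numeric vector of histogram edges
#'   (default `seq(3, 8, by = 0.5)`).
#' @param denominator "all" or "identified".
#' @return List with `proportions` (class, count, denominator, percent),
#'   `histogram` (klass, bin_start, bin_end, count, percent within class),
#'   `n_promoters`, `n_identified`.
#' @export
tabulate_calls <- function(promoter_calls, bin_edges = seq(3, 8, by = 0.5),
                           denominator = c("all", "identified")) {
  denominator <- match.arg(denominator)
  assert_columns(promoter_calls, c("klass", "identified",
                                   "peakscore_nor", "peakscore_pv"),
                 "promoter_calls")
  if (nrow(promoter_calls) == 0L) stop("no promoter calls", call. = FALSE)
  n_all <- nrow(promoter_calls)
  n_ident <- sum(promoter_calls$identified)
  denom_n <- if (denominator == "all") n_all else n_ident
  classes <- c("te_hypomethylated", "te_hypermethylated")
  counts <- vapply(classes, function(k) sum(promoter_calls$klass == k),
                   integer(1))
  proportions <- data.frame(
    klass = classes,
    count = as.integer(counts),
    denominator = denom_n,
    percent = if (denom_n > 0) 100 * counts / denom_n else rep(0, 2),
    stringsAsFactors = FALSE
  )
  edges <- c(bin_edges, Inf)
  hist_rows <- lapply(classes, function(k) {
    sel <- promoter_calls$klass == k
    present <- if (k == "te_hypomethylated") {
      promoter_calls$peakscore_pv[sel]
    } else {
      promoter_calls$peakscore_nor[sel]
    }
    cnt <- as.integer(table(cut(present, edges, right = FALSE)))
    data.frame(
      klass = k,
      bin_start = edges[-length(edges)],
      bin_end = edges[-1],
      count = cnt,
      percent = if (sum(cnt) > 0) 100 * cnt / sum(cnt) else rep(0, length(cnt)),
      stringsAsFactors = FALSE
    )
  })
  histogram <- do.call(rbind, hist_rows)
  rownames(histogram) <- NULL
  list(proportions = proportions, histogram = histogram,
       n_promoters = n_all, n_identified = n_ident)
}

#' Sensitivity and precision against planted truth
#'
#' Compares calls with the planted truth. A true positive is a unit called
#' differential with the same class it was planted with; sensitivity is
#' TP / planted differential, precision is TP / called differential.
#' Accepts promoter-level calls (matched by accession) or gene-level calls
#' (matched by gene symbol).
#'
#' @param calls Output of [classify_promoters()] or [summarize_genes()].
#' @param truth Output of [plant_truth()].
#' @return List with overall `sensitivity` and `precision`, counts, and a
#'   per-class data frame `per_class`.
#' @export
recovery_metrics <- function(calls, truth) {
  if ("accession" %in% names(calls)) {
    key <- truth$class[match(calls$accession, truth$accession)]
  } else {
    key <- truth$class[match(calls$gene_symbol, truth$gene_symbol)]
  }
  if (anyNA(key)) stop("calls contain units absent from truth", call. = FALSE)
  planted <- key != "none"
  called <- calls$klass != "unclassified"
  tp <- called & planted & calls$klass == key
  per_class <- do.call(rbind, lapply(
    c("te_hypomethylated", "te_hypermethylated"), function(k) {
      npl <- sum(key == k)
      ncl <- sum(calls$klass == k)
      ntp <- sum(tp & key == k)
      data.frame(klass = k, n_planted = npl, n_called = ncl, n_tp = ntp,
                 sensitivity = if (npl > 0) ntp / npl else NA_real_,
                 precision = if (ncl > 0) ntp / ncl else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  list(
    sensitivity = if (sum(planted) > 0) sum(tp) / sum(planted) else NA_real_,
    precision = if (sum(called) > 0) sum(tp) / sum(called) else NA_real_,
    n_planted = sum(planted), n_called = sum(called), n_tp = sum(tp),
    per_class = per_class
  )
}
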