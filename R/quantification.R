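# Validation-assay calculators: MeDIP-qPCR relative enrichment and
# MethyLight percent methylation (PMR), with control-gene sanity checks.
# PCR efficiency is fixed at 2 (perfect doubling), as the formulas assume.

check_ct <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) {
    !is.na(x) & (!is.finite(x) | x <= 0 | x >= 45)
  } else {
    !is.finite(x) | x <= 0 | x >= 45
  }
  if (any(bad)) {
    stop(sprintf("'%s' contains Ct values outside (0, 45)", name),
         call. = FALSE)
  }
  invisible(x)
}

#' MeDIP-qPCR percent enrichment
#'
#' Relative quantity of immunoprecipitated to Input DNA:
#' `percent IP/Input = 2^-(Ct_IP - Ct_Input) * dilution_factor * 100`.
#' Strictly decreasing in `ct_ip`, strictly increasing in `ct_input` and in
#' the dilution factor. Vectorized.
#'
#' @param ct_ip,ct_input Quantification cycles, in (0, 45).
#' @param dilution_factor Dilution factor of the Input DNA (> 0); no
#'   default, it is an assay-specific input.
#' @return Percent enrichment.
#' @export
medip_percent <- function(ct_ip, ct_input, dilution_factor) {
  check_ct(ct_ip, "ct_ip")
  check_ct(ct_input, "ct_input")
  if (any(!is.finite(dilution_factor)) || any(dilution_factor <= 0)) {
    stop("dilution_factor must be positive", call. = FALSE)
  }
  2^(-(ct_ip - ct_input)) * dilution_factor * 100
}

#' MethyLight percent of methylated reference (PMR)
#'
#' `PMR = 2^-ddCt * 100` with
#' `ddCt = (Ct_target - Ct_reference)_sample -
#'         (Ct_target - Ct_reference)_fully-methylated`.
#' Invariant to adding a constant to both Cts of the same specimen
#' (reference normalization). Values above 100% (possible with noisy Cts)
#' are returned as computed; table-level wrappers flag them. Vectorized;
#' missing sample Cts (censored loci) propagate NA.
#'
#' @param ct_target_sample,ct_reference_sample Sample reaction Cts.
#' @param ct_target_fullmeth,ct_reference_fullmeth Fully methylated control
#'   DNA Cts (required).
#' @return Percent methylation.
#' @export
methylight_pmr <- function(ct_target_sample, ct_reference_sample,
                           ct_target_fullmeth, ct_reference_fullmeth) {
  if (missing(ct_target_fullmeth) || missing(ct_reference_fullmeth) ||
      anyNA(ct_target_fullmeth) || anyNA(ct_reference_fullmeth)) {
    stop("fully methylated control Cts are required", call. = FALSE)
  }
  check_ct(ct_target_sample, "ct_target_sample", allow_na = TRUE)
  check_ct(ct_reference_sample, "ct_reference_sample")
  check_ct(ct_target_fullmeth, "ct_target_fullmeth")
  check_ct(ct_reference_fullmeth, "ct_reference_fullmeth")
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_fullmeth - ct_reference_fullmeth)
  2^(-ddct) * 100
}

#' Quantify a MeDIP-qPCR Ct table
#'
#' @param records Data frame with `locus_id`, `ct_ip`, `ct_input`,
#'   `dilution_factor`. Replicate rows per locus are averaged on the Ct
#'   scale (arithmetic mean) before the formula.
#' @return Data frame with `locus_id`, averaged Cts, `dilution_factor` and
#'   `percent_ip_input`.
#' @export
quantify_medip <- function(records) {
  assert_columns(records, c("locus_id", "ct_ip", "ct_input",
                            "dilution_factor"), "qPCR records")
  agg <- stats::aggregate(
    records[, c("ct_ip", "ct_input", "dilution_factor")],
    by = list(locus_id = records$locus_id), FUN = mean
  )
  agg$percent_ip_input <- medip_percent(agg$ct_ip, agg$ct_input,
                                        agg$dilution_factor)
  agg
}

#' Quantify a MethyLight Ct table
#'
#' Censored loci (no amplification of the methylation-specific reaction,
#' `censored = TRUE` or missing sample Ct) get `pmr_percent = NA`. PMR
#' values above 100% are kept but flagged (`flag_over_100`).
#'
#' @param records Data frame with `locus_id`, `ct_target_sample`,
#'   `ct_reference_sample`, `ct_target_fullmeth`, `ct_reference_fullmeth`,
#'   optionally `censored`.
#' @return The records with added `pmr_percent` and `flag_over_100`.
#' @export
quantify_methylight <- function(records) {
  assert_columns(records, c("locus_id", "ct_target_sample",
                            "ct_reference_sample", "ct_target_fullmeth",
                            "ct_reference_fullmeth"), "MethyLight records")
  out <- records
  censored <- if ("censored" %in% names(records)) {
    records$censored | is.na(records$ct_target_sample)
  } else {
    is.na(records$ct_target_sample)
  }
  out$pmr_percent <- methylight_pmr(records$ct_target_sample,
                                    records$ct_reference_sample,
                                    records$ct_target_fullmeth,
                                    records$ct_reference_fullmeth)
  out$pmr_percent[censored] <- NA_real_
  out$flag_over_100 <- !is.na(out$pmr_percent) & out$pmr_percent > 100
  out
}

#' Expected behaviour of assay controls
#'
#' @param negative_control_id Locus expected unmethylated (e.g. a GAPDH-like
#'   promoter).
#' @param positive_control_id Optional locus expected methylated (e.g. an
#'   H19-like imprinted promoter).
#' @param max_negative_pct Maximum tolerated percent methylation/enrichment
#'   at the negative control.
#' @param min_delta_ct_specificity Minimum Ct margin between unmethylated
#'   and fully methylated control DNA for a methylation-specific reaction
#'   (default 5 cycles).
#' @return An object of class `control_expectation`.
#' @export
control_expectation <- function(negative_control_id,
                                positive_control_id = NA_character_,
                                max_negative_pct = 0.01,
                                min_delta_ct_specificity = 5) {
  assert_scalar_number(max_negative_pct, "max_negative_pct", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(min_delta_ct_specificity, "min_delta_ct_specificity",
                       lower = 0, strict_lower = TRUE)
  structure(list(
    negative_control_id = negative_control_id,
    positive_control_id = positive_control_id,
    max_negative_pct = max_negative_pct,
    min_delta_ct_specificity = min_delta_ct_specificity
  ), class = "control_expectation")
}

#' Check assay controls
#'
#' Report-only QC: flags runs where the negative-control percent exceeds
#' `max_negative_pct`, and methylation-specific reactions whose specificity
#' margin (Ct on unmethylated minus Ct on fully methylated control DNA)
#' falls below `min_delta_ct_specificity`.
#'
#' @param percents Data frame with `locus_id` and `percent` (from
#'   [quantify_medip()] or [quantify_methylight()]); may be empty or NULL.
#' @param specificity Data frame with `locus_id` and `delta_ct_margin`;
#'   may be empty or NULL.
#' @param expectation A [control_expectation()].
#' @return Data frame report: `check`, `locus_id`, `value`, `threshold`,
#'   `pass`.
#' @export
check_assay_controls <- function(percents = NULL, specificity = NULL,
                                 expectation) {
  stopifnot(inherits(expectation, "control_expectation"))
  rows <- list()
  if (!is.null(percents) && nrow(percents) > 0L) {
    assert_columns(percents, c("locus_id", "percent"), "percents")
    neg <- percents[percents$locus_id == expectation$negative_control_id, ,
                    drop = FALSE]
    if (nrow(neg)) {
      rows[[length(rows) + 1L]] <- data.frame(
        check = "negative_control",
        locus_id = neg$locus_id,
        value = neg$percent,
        threshold = expectation$max_negative_pct,
        pass = neg$percent <= expectation$max_negative_pct,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(specificity) && nrow(specificity) > 0L) {
    assert_columns(specificity, c("locus_id", "delta_ct_margin"),
                   "specificity")
    rows[[length(rows) + 1L]] <- data.frame(
      check = "specificity_margin",
      locus_id = specificity$locus_id,
      value = specificity$delta_ct_margin,
      threshold = expectation$min_delta_ct_specificity,
      pass = specificity$delta_ct_margin >= expectation$min_delta_ct_specificity,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(check = character(), locus_id = character(),
                      value = numeric(), threshold = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
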