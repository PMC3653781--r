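# Validation assays on selected promoters: MeDIP-qPCR relative enrichment
# (2^-dCt * dilution * 100%) and MethyLight percent-methylated-reference
# (2^-ddCt * 100%), with a GAPDH-like unmethylated negative control and an
# H19-like imprinted positive control, and the 5-cycle specificity check
# on the methylation-specific reactions.

source("analysis/00_config.R")

truth <- read_tsv_plain(file.path(DATA_DIR, "truth.tsv"))

# 10 validation loci: 5 planted hypo-, 3 hypermethylated, 2 controls.
pick <- function(klass, n) head(truth$gene_symbol[truth$class == klass], n)
meth_frac_nor <- function(klass) {
  # Nor methylated fraction = f * 1{TE meth} + (1 - f) * 1{bg meth}
  switch(klass, te_hypomethylated = 0.27, te_hypermethylated = 0.73, none = 0)
}
loci <- data.frame(
  locus_id = c(pick("te_hypomethylated", 5), pick("te_hypermethylated", 3),
               "NEG_CTRL_GAPDH_LIKE", "POS_CTRL_H19_LIKE"),
  klass = c(rep("te_hypomethylated", 5), rep("te_hypermethylated", 3),
            "negative_control", "positive_control"),
  stringsAsFactors = FALSE
)
loci$methylation <- c(rep(0.27, 5), rep(0.73, 3), 1e-5, 0.5)
loci$enrichment <- pmax(loci$methylation, 1e-5)

tabs <- simulate_ct_tables(loci, assay_params(noise_sd = 0.15, seed = SEED))
qpcr <- quantify_medip(tabs$qpcr)
ml <- quantify_methylight(tabs$methylight)

report <- check_assay_controls(
  percents = data.frame(locus_id = ml$locus_id, percent = ml$pmr_percent),
  specificity = data.frame(
    locus_id = ml$locus_id,
    delta_ct_margin = ml$ct_target_unmeth - ml$ct_target_fullmeth),
  expectation = control_expectation(negative_control_id = "NEG_CTRL_GAPDH_LIKE",
                                    positive_control_id = "POS_CTRL_H19_LIKE")
)

merged <- merge(loci[, c("locus_id", "klass", "methylation")],
                ml[, c("locus_id", "pmr_percent", "flag_over_100")],
                by = "locus_id")
merged <- merge(merged, qpcr[, c("locus_id", "percent_ip_input")],
                by = "locus_id")
cat("Per-locus quantification (planted methylation vs measured):\n")
print(merged)
cat(sprintf("Assay controls: %d/%d checks passed\n",
            sum(report$pass), nrow(report)))

write_tsv_plain(tabs$qpcr, file.path(DATA_DIR, "qpcr_ct.tsv"))
write_tsv_plain(tabs$methylight, file.path(DATA_DIR, "methylight_ct.tsv"))
write_tsv_plain(merged, file.path(OUT_DIR, "quantification.tsv"))
write_tsv_plain(report, file.path(OUT_DIR, "assay_controls.tsv"))
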