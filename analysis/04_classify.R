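# Map peaks to promoters and apply the two-condition peakscore criteria:
# TE-specific hypomethylated = peak present in PV (score > 3.0) and absent
# in Nor (score < 2.0); hypermethylated = the mirror image. Summarize
# promoters to genes, tabulate class proportions and peakscore histograms,
# and measure recovery of the planted truth.

source("analysis/00_config.R")

annotation <- read_annotation(file.path(DATA_DIR, "annotation.tsv"))
truth <- read_tsv_plain(file.path(DATA_DIR, "truth.tsv"))
peaks_nor <- read_tsv_plain(file.path(DATA_DIR, "peaks_nor.tsv"))
peaks_pv <- read_tsv_plain(file.path(DATA_DIR, "peaks_pv.tsv"))

scores <- assign_promoter_scores(peaks_nor, peaks_pv, annotation)
calls <- classify_promoters(scores, classification_thresholds())
genes <- summarize_genes(calls)
tabs <- tabulate_calls(calls)
metrics <- recovery_metrics(calls, truth)

cat(sprintf("%d/%d promoters identified (>=1 peak in either condition)\n",
            tabs$n_identified, tabs$n_promoters))
print(tabs$proportions)
cat(sprintf("Gene level: %d hypo-, %d hypermethylated genes\n",
            sum(genes$klass == "te_hypomethylated"),
            sum(genes$klass == "te_hypermethylated")))
cat(sprintf("Planted-truth recovery: sensitivity %.3f, precision %.3f\n",
            metrics$sensitivity, metrics$precision))
print(metrics$per_class)

write_tsv_plain(calls, file.path(OUT_DIR, "promoter_calls.tsv"))
write_tsv_plain(genes, file.path(OUT_DIR, "gene_calls.tsv"))
write_tsv_plain(tabs$proportions, file.path(OUT_DIR, "class_proportions.tsv"))
write_tsv_plain(tabs$histogram, file.path(OUT_DIR, "peakscore_histogram.tsv"))
write_tsv_plain(metrics$per_class, file.path(OUT_DIR, "recovery_metrics.tsv"))
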