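# Category over-representation of the recovered TE-specific hypomethylated
# gene list (Fisher exact, BH-corrected) over a synthetic category map with
# one planted reproduction-like category. The planted category should rank
# first; random categories should not reach significance.

source("analysis/00_config.R")

truth <- read_tsv_plain(file.path(DATA_DIR, "truth.tsv"))
genes <- read_tsv_plain(file.path(OUT_DIR, "gene_calls.tsv"))
hypo_genes <- genes$gene_symbol[genes$klass == "te_hypomethylated"]

cat_map <- simulate_category_map(truth, seed = SEED)
results <- enrich(hypo_genes, cat_map$categories, cat_map$universe)

cat(sprintf("Enrichment over %d categories for %d recovered hypomethylated genes\n",
            length(cat_map$categories), length(hypo_genes)))
print(head(results, 5))
stopifnot(results$category_id[1] == "SEXUAL_REPRODUCTION_LIKE")
cat(sprintf("Planted category q = %.3g; next-best q = %.3g\n",
            results$q_value[1],
            if (nrow(results) > 1) results$q_value[2] else NA))

write_tsv_plain(results, file.path(OUT_DIR, "enrichment.tsv"))
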