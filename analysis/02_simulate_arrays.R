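# Simulate the promoter array study: 1000 promoters tiled at 100 bp,
# planted TE-specific methylation classes (9.71% hypo-, 3.53%
# hypermethylated, 9.6% methylated in both sources), and one pooled
# MeDIP-chip profile per condition under the two-source cfsDNA mixture
# (73% TE-derived DNA in Nor, none in PV).

source("analysis/00_config.R")

annotation <- generate_annotation(STUDY_CONFIG)
truth <- plant_truth(annotation, STUDY_CONFIG)
profiles <- simulate_arrays(annotation, truth, STUDY_MIXTURE, STUDY_CONFIG)

cat(sprintf("Simulated %d promoters (%d probes/condition) on %d chromosomes\n",
            nrow(annotation), nrow(profiles$nor),
            length(unique(annotation$chrom))))
print(table(truth$class))

write_annotation(annotation, file.path(DATA_DIR, "annotation.tsv"))
write_bed(transform(annotation, name = accession, score = 0),
          file.path(DATA_DIR, "annotation.bed"))
write_tsv_plain(truth, file.path(DATA_DIR, "truth.tsv"))
write_profile(profiles$nor, file.path(DATA_DIR, "profile_nor.tsv"))
write_profile(profiles$pv, file.path(DATA_DIR, "profile_pv.tsv"))
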