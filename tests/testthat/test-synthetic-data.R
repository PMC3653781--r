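test_that("promoter windows are strand-oriented, non-overlapping and seeded", {
  cfg <- simulation_config(n_genes = 50, seed = 3)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 50)
  plus <- ann$strand == "+"
  expect_true(all(ann$start[plus] == ann$tss[plus] - 2200))
  expect_true(all(ann$end[plus] == ann$tss[plus] + 500))
  expect_true(all(ann$start[!plus] == ann$tss[!plus] - 500))
  expect_true(all(ann$end[!plus] == ann$tss[!plus] + 2200))
  for (ch in split(ann, ann$chrom)) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1) expect_true(all(ch$start[-1] >= ch$end[-nrow(ch)]))
  }
  expect_identical(ann, generate_annotation(simulation_config(n_genes = 50, seed = 3)))
  expect_false(identical(ann$strand,
                         generate_annotation(simulation_config(n_genes = 50, seed = 4))$strand))
  expect_error(simulation_config(n_genes = 0), "n_genes")
})

test_that("planted class counts follow rounded proportions and are seeded", {
  cfg <- simulation_config(n_genes = 1000, seed = 7)
  truth <- plant_truth(generate_annotation(cfg), cfg)
  expect_equal(sum(truth$class == "te_hypomethylated"), 97)
  expect_equal(sum(truth$class == "te_hypermethylated"), 35)
  expect_equal(sum(truth$state_te == "methylated" & truth$state_bg == "methylated"), 96)
  hypo <- truth$class == "te_hypomethylated"
  expect_true(all(truth$state_te[hypo] == "unmethylated"))
  expect_true(all(truth$state_bg[hypo] == "methylated"))
  hyper <- truth$class == "te_hypermethylated"
  expect_true(all(truth$state_te[hyper] == "methylated"))
  expect_true(all(truth$state_bg[hyper] == "unmethylated"))
  expect_identical(truth, plant_truth(generate_annotation(cfg), cfg))

  flat <- simulation_config(n_genes = 40, fraction_te_hypo = 0,
                            fraction_te_hyper = 0,
                            fraction_background_methylated = 0, seed = 1)
  truth0 <- plant_truth(generate_annotation(flat), flat)
  expect_true(all(truth0$class == "none"))
  expect_true(all(truth0$state_te == "unmethylated"))
})

test_that("mixture endpoints: pure TE source in Nor, pure background in PV", {
  cfg <- simulation_config(n_genes = 3, seed = 2)
  ann <- generate_annotation(cfg)
  truth <- data.frame(gene_symbol = ann$gene_symbol, accession = ann$accession,
                      state_te = "unmethylated", state_bg = "methylated",
                      class = "te_hypomethylated", stringsAsFactors = FALSE)
  mix <- mixture_model(fraction_te = 1, sigma_probe = 1e-9, seed = 2)
  prof <- simulate_arrays(ann, truth, mix, cfg)
  expect_lt(max(abs(prof$nor$value - 0)), 1e-6)
  expect_lt(max(abs(prof$pv$value - 1.5)), 1e-6)
  expect_error(simulate_arrays(ann[0, ], truth, mix, cfg), "empty")
})

test_that("expected Nor probe mean over hypo promoters matches the closed form", {
  cfg <- simulation_config(n_genes = 1000, seed = 5)
  ann <- generate_annotation(cfg)
  truth <- plant_truth(ann, cfg)
  mix <- mixture_model(seed = 5)
  prof <- simulate_arrays(ann, truth, mix, cfg)
  hypo_acc <- truth$accession[truth$class == "te_hypomethylated"]
  hypo_chrom_start <- ann[ann$accession %in% hypo_acc, c("chrom", "start", "end")]
  in_hypo <- rep(FALSE, nrow(prof$nor))
  for (r in seq_len(nrow(hypo_chrom_start))) {
    in_hypo <- in_hypo | (prof$nor$chrom == hypo_chrom_start$chrom[r] &
                            prof$nor$start >= hypo_chrom_start$start[r] &
                            prof$nor$start < hypo_chrom_start$end[r])
  }
  # E = (1 - f) * mu_meth = 0.27 * 1.5 = 0.405; component-model probe SD
  # ~0.78 over ~2600 probes => MC error ~0.015
  expect_equal(mean(prof$nor$value[in_hypo]), 0.405, tolerance = 0.05 / 0.405)
  expect_equal(mean(prof$pv$value[in_hypo]), 1.5, tolerance = 0.02)
  # determinism of the whole draw
  prof2 <- simulate_arrays(ann, truth, mix, cfg)
  expect_identical(prof$nor$value, prof2$nor$value)
})

test_that("the mean signal model applies a uniform intermediate shift", {
  cfg <- simulation_config(n_genes = 2, seed = 9)
  ann <- generate_annotation(cfg)
  truth <- data.frame(gene_symbol = ann$gene_symbol, accession = ann$accession,
                      state_te = "unmethylated", state_bg = "methylated",
                      class = "te_hypomethylated", stringsAsFactors = FALSE)
  mix <- mixture_model(sigma_probe = 1e-9, signal_model = "mean", seed = 9)
  prof <- simulate_arrays(ann, truth, mix, cfg)
  expect_lt(max(abs(prof$nor$value - 0.405)), 1e-6)
})

test_that("Ct tables invert the quantification formulas and flag censoring", {
  loci <- data.frame(locus_id = c("A", "B", "NEG"),
                     enrichment = c(1, 0.25, 0.001),
                     methylation = c(0.5, 1, 0),
                     stringsAsFactors = FALSE)
  tabs <- simulate_ct_tables(loci, assay_params(noise_sd = 0, dilution_factor = 0.5))
  expect_equal(medip_percent(tabs$qpcr$ct_ip, tabs$qpcr$ct_input,
                             tabs$qpcr$dilution_factor),
               100 * loci$enrichment, tolerance = 1e-12)
  pmr <- methylight_pmr(tabs$methylight$ct_target_sample,
                        tabs$methylight$ct_reference_sample,
                        tabs$methylight$ct_target_fullmeth,
                        tabs$methylight$ct_reference_fullmeth)
  expect_equal(pmr[1:2], c(50, 100), tolerance = 1e-12)
  expect_true(tabs$methylight$censored[3])
  expect_true(is.na(tabs$methylight$ct_target_sample[3]))
  # specificity margin of the simulated assay clears the 5-cycle rule
  margin <- tabs$methylight$ct_target_unmeth - tabs$methylight$ct_target_fullmeth
  expect_true(all(margin > 5))
  expect_identical(tabs, simulate_ct_tables(loci, assay_params(noise_sd = 0,
                                                               dilution_factor = 0.5)))
  expect_error(simulate_ct_tables(transform(loci, enrichment = c(1, 0, 1))),
               "positive")
})

test_that("cohort draws are positive, seeded, and near the planted means", {
  coh <- simulate_cohort(seed = 42)
  expect_identical(coh, simulate_cohort(seed = 42))
  expect_true(all(coh$concentration > 0))
  expect_equal(sum(coh$group == "Nor"), 12)
  expect_equal(sum(coh$group == "PV"), 11)
  expect_equal(mean(coh$concentration[coh$group == "Nor"]), 1.23, tolerance = 0.3)
})
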