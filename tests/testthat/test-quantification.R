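test_that("MeDIP-qPCR enrichment follows the 2^-dCt formula", {
  expect_equal(medip_percent(30, 30, 1), 100)
  expect_equal(medip_percent(31, 30, 1), 50)
  expect_equal(medip_percent(28, 30, 0.1), 40)
  expect_error(medip_percent(30, 30, 0), "dilution")
  expect_error(medip_percent(50, 30, 1), "Ct")

  # strict monotonicity in each argument
  expect_lt(medip_percent(30.5, 30, 1), medip_percent(30, 30, 1))
  expect_gt(medip_percent(30, 30.5, 1), medip_percent(30, 30, 1))
  expect_gt(medip_percent(30, 30, 2), medip_percent(30, 30, 1))
})

test_that("MethyLight PMR follows the 2^-ddCt formula and normalizes", {
  expect_equal(methylight_pmr(30, 28, 27, 25), 100)  # sample dCt == control dCt
  expect_equal(methylight_pmr(32, 28, 27, 25), 25)   # 2 cycles beyond control
  # adding a constant to both Cts of one specimen changes nothing
  expect_equal(methylight_pmr(32 + 3, 28 + 3, 27, 25),
               methylight_pmr(32, 28, 27, 25))
  expect_error(methylight_pmr(30, 28), "control")
  expect_true(is.na(methylight_pmr(NA, 28, 27, 25)))
})

test_that("table-level quantifiers average replicates and flag outliers", {
  reps <- data.frame(locus_id = c("L1", "L1"), ct_ip = c(29, 31),
                     ct_input = c(30, 30), dilution_factor = 1)
  q <- quantify_medip(reps)
  expect_equal(nrow(q), 1)
  expect_equal(q$percent_ip_input, 100)  # mean Ct 30 vs 30

  ml <- data.frame(locus_id = c("A", "B"),
                   ct_target_sample = c(28, NA),
                   ct_reference_sample = c(28, 28),
                   ct_target_fullmeth = c(27, 27),
                   ct_reference_fullmeth = c(25, 25),
                   censored = c(FALSE, TRUE))
  out <- quantify_methylight(ml)
  expect_equal(out$pmr_percent[1], 400)
  expect_true(out$flag_over_100[1])
  expect_true(is.na(out$pmr_percent[2]))
})

test_that("zero-noise Ct tables round-trip planted truth below 1e-9", {
  loci <- data.frame(locus_id = sprintf("L%d", 1:5),
                     enrichment = c(1, 0.5, 0.25, 0.1, 0.01),
                     methylation = c(1, 0.5, 0.25, 0.1, 0.01))
  tabs <- simulate_ct_tables(loci, assay_params(noise_sd = 0, dilution_factor = 2))
  q <- quantify_medip(tabs$qpcr)
  expect_lt(max(abs(q$percent_ip_input[match(loci$locus_id, q$locus_id)] -
                      100 * loci$enrichment)), 1e-9)
  ml <- quantify_methylight(tabs$methylight)
  expect_lt(max(abs(ml$pmr_percent - 100 * loci$methylation)), 1e-9)
})

test_that("assay control checks flag contamination and weak specificity", {
  expectation <- control_expectation(negative_control_id = "NEG",
                                     positive_control_id = "POS",
                                     max_negative_pct = 0.01)
  pct <- data.frame(locus_id = c("NEG", "POS"), percent = c(0.001, 59.3))
  spec <- data.frame(locus_id = c("L1", "L2"), delta_ct_margin = c(8.1, 4.2))
  report <- check_assay_controls(pct, spec, expectation)
  expect_true(report$pass[report$check == "negative_control"])
  expect_identical(report$pass[report$check == "specificity_margin"],
                   c(TRUE, FALSE))

  dirty <- data.frame(locus_id = "NEG", percent = 0.5)
  expect_false(check_assay_controls(dirty, NULL, expectation)$pass)

  empty <- check_assay_controls(NULL, NULL, expectation)
  expect_equal(nrow(empty), 0)
})
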