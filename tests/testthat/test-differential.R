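scores_df <- function(nor, pv, gene = NULL, acc = NULL) {
  n <- length(nor)
  data.frame(
    accession = acc %||% sprintf("NMS%03d", seq_len(n)),
    gene_symbol = gene %||% sprintf("G%03d", seq_len(n)),
    peakscore_nor = nor, peakscore_pv = pv,
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("two-condition criteria classify with strict inequalities", {
  calls <- classify_promoters(scores_df(
    nor = c(1.0, 2.5, 1.0, 4.0, 2.0, 0.0),
    pv  = c(3.5, 3.5, 3.0, 0.0, 3.5, 0.0)
  ))
  expect_identical(calls$klass, c(
    "te_hypomethylated",  # present in PV, absent in Nor
    "unclassified",       # Nor score 2.5 not below 2.0
    "unclassified",       # PV score exactly 3.0: "more than" is strict
    "te_hypermethylated", # present in Nor, vasectomy abolished in PV
    "unclassified",       # Nor score exactly 2.0: "less than" is strict
    "unclassified"        # no signal anywhere
  ))
  expect_identical(calls$identified,
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("peaks map to promoters by >=1 bp overlap with max aggregation", {
  ann <- data.frame(
    gene_symbol = c("GA", "GB"), accession = c("A1", "B1"),
    chrom = "chrS1", tss = c(12200, 52200), strand = "+",
    start = c(10000L, 50000L), end = c(12700L, 52700L),
    stringsAsFactors = FALSE
  )
  peaks_pv <- data.frame(
    chrom = c("chrS1", "chrS1", "chrS1", "chrZ"),
    start = c(10500L, 11000L, 30000L, 100L),
    end = c(10800L, 11600L, 30500L, 900L),
    probe_count = 3L,
    peakscore = c(3.2, 4.1, 9.9, 9.9),
    stringsAsFactors = FALSE
  )
  expect_warning(
    scores <- assign_promoter_scores(NULL, peaks_pv, ann),
    "chrZ"
  )
  expect_equal(nrow(scores), 2)           # every promoter appears
  expect_equal(scores$peakscore_pv, c(4.1, 0))  # max rule; no-overlap peak ignored
  expect_equal(scores$peakscore_nor, c(0, 0))

  # a peak straddling the promoter edge still counts (1 bp overlap)
  edge <- data.frame(chrom = "chrS1", start = 12699L, end = 13200L,
                     probe_count = 2L, peakscore = 5.0)
  s2 <- assign_promoter_scores(edge, NULL, ann)
  expect_equal(s2$peakscore_nor, c(5, 0))
})

test_that("gene summarization takes the unique class and neutralizes conflicts", {
  calls <- classify_promoters(scores_df(
    nor = c(1, 1, 4, 1, 1),
    pv  = c(4, 1, 1, 4, 1),
    gene = c("G1", "G1", "G2", "G2", "G3"),
    acc = sprintf("A%d", 1:5)
  ))
  genes <- summarize_genes(calls)
  g <- function(x) genes[genes$gene_symbol == x, ]
  expect_identical(g("G1")$klass, "te_hypomethylated")  # hypo + unclassified
  expect_identical(g("G1")$supporting_accessions, "A1")
  expect_identical(g("G2")$klass, "unclassified")       # hypo + hyper conflict
  expect_true(g("G2")$conflict_flag)
  expect_identical(g("G3")$klass, "unclassified")
  expect_false(g("G3")$conflict_flag)
})

test_that("tabulation counts classes and bins present-condition peakscores", {
  nor <- c(rep(1, 10), rep(4, 4), rep(0, 86))
  pv <- c(rep(3.2, 10), rep(0, 4), rep(0, 86))
  tabs <- tabulate_calls(classify_promoters(scores_df(nor, pv)))
  expect_equal(tabs$proportions$percent, c(10, 4))
  expect_equal(tabs$n_identified, 14)
  hypo_hist <- tabs$histogram[tabs$histogram$klass == "te_hypomethylated", ]
  expect_equal(hypo_hist$count[1], 10L)  # all hypo scores in [3.0, 3.5)
  expect_equal(hypo_hist$percent[1], 100)

  ident <- tabulate_calls(classify_promoters(scores_df(nor, pv)),
                          denominator = "identified")
  expect_equal(ident$proportions$percent, 100 * c(10, 4) / 14)

  none <- tabulate_calls(classify_promoters(scores_df(rep(0, 5), rep(0, 5))))
  expect_equal(none$proportions$percent, c(0, 0))
  expect_true(all(none$histogram$count == 0))
})

test_that("swapping the condition labels swaps the two differential classes", {
  nor <- withr::with_seed(11, runif(500, 0, 6))
  pv <- withr::with_seed(12, runif(500, 0, 6))
  fwd <- classify_promoters(scores_df(nor, pv))
  rev <- classify_promoters(scores_df(pv, nor))
  expect_equal(sum(fwd$klass == "te_hypomethylated"),
               sum(rev$klass == "te_hypermethylated"))
  expect_equal(sum(fwd$klass == "te_hypermethylated"),
               sum(rev$klass == "te_hypomethylated"))
  expect_identical(which(fwd$klass == "te_hypomethylated"),
                   which(rev$klass == "te_hypermethylated"))
})

test_that("recovery metrics count class-matched true positives", {
  truth <- data.frame(
    gene_symbol = sprintf("G%03d", 1:4), accession = sprintf("NMS%03d", 1:4),
    state_te = "unmethylated", state_bg = "methylated",
    class = c("te_hypomethylated", "te_hypomethylated",
              "te_hypermethylated", "none"),
    stringsAsFactors = FALSE
  )
  calls <- classify_promoters(scores_df(
    nor = c(1, 1, 1, 1),
    pv = c(4, 1, 4, 4)
  ))
  # calls: hypo, none, hypo(mismatch vs planted hyper), hypo(false positive)
  m <- recovery_metrics(calls, truth)
  expect_equal(m$n_tp, 1)
  expect_equal(m$sensitivity, 1 / 3)
  expect_equal(m$precision, 1 / 3)
})
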