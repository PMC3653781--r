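test_that("one-sided KS statistic honors direction, ties and separation", {
  # window drawn identically to background: no separation
  same <- ks_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d_statistic, 0)
  expect_equal(same$p_value, 1)

  # complete separation above: D = 1, p = permutation-null mass of D = 1
  sep <- ks_one_sided(c(10, 11, 12), c(0, 1, 2, 3, 4))
  expect_equal(sep$d_statistic, 1)
  expect_identical(sep$method, "exact")
  expect_equal(sep$p_value, 1 / choose(8, 3))
  expect_equal(sep$p_value, oracle_perm_p(c(10, 11, 12), c(0, 1, 2, 3, 4)))

  # window entirely below background: one-sided (greater) says nothing
  below <- ks_one_sided(c(-6, -5), 0:9)
  expect_equal(below$d_statistic, 0)
  expect_equal(below$p_value, 1)

  expect_error(ks_one_sided(numeric(), 1:5), "non-empty")
  expect_error(ks_one_sided(1, 2), "at least 2")
})

test_that("exact p equals exhaustive permutation enumeration on small pools", {
  pools <- list(
    withr::with_seed(1, rnorm(8)),
    c(1, 1, 2, 2, 3, 3, 4, 4)  # heavy ties
  )
  for (pooled in pools) {
    n_tot <- length(pooled)
    for (m in 1:(n_tot - 2)) {
      splits <- utils::combn(n_tot, m)
      for (j in seq_len(ncol(splits))) {
        w <- pooled[splits[, j]]
        b <- pooled[-splits[, j]]
        got <- ks_one_sided(w, b)
        expect_identical(got$method, "exact")
        expect_equal(got$p_value, oracle_perm_p(w, b))
        expect_equal(got$d_statistic, oracle_dplus(w, b))
      }
    }
  }
  # a larger pool, sampled splits
  pooled <- withr::with_seed(2, rnorm(12))
  for (m in c(3, 6)) {
    for (j in 1:10) {
      sel <- withr::with_seed(100 * m + j, sample(12, m))
      w <- pooled[sel]
      b <- pooled[-sel]
      expect_equal(ks_one_sided(w, b)$p_value, oracle_perm_p(w, b))
    }
  }
})

test_that("shifting the window up never decreases D", {
  for (i in 1:20) {
    w <- withr::with_seed(i, rnorm(5))
    b <- withr::with_seed(1000 + i, rnorm(30))
    d0 <- ks_one_sided(w, b)$d_statistic
    for (shift in c(0.1, 1, 3)) {
      expect_gte(ks_one_sided(w + shift, b)$d_statistic, d0)
    }
  }
})

test_that("scan results agree with direct per-window KS calls", {
  prof <- make_profile(withr::with_seed(4, rnorm(15)))
  win <- scan_windows(prof, peak_params())
  for (i in seq_len(nrow(win))) {
    members <- seq.int(win$first_probe[i], win$last_probe[i])
    ref <- ks_one_sided(prof$value[members], prof$value[-members])
    expect_equal(win$d_statistic[i], ref$d_statistic)
    expect_equal(win$p_value[i], ref$p_value)
  }
  expect_error(scan_windows(make_profile(rnorm(9))), "fewer than 10")
})

test_that("a window narrower than the probe spacing still scans", {
  prof <- make_profile(withr::with_seed(5, rnorm(20)), spacing = 100)
  win <- scan_windows(prof, peak_params(window_width = 50))
  expect_true(all(win$n_probes == 1L))
  expect_equal(nrow(win), 20)
})

test_that("a planted enriched block carries the top window score and a peak", {
  vals <- withr::with_seed(6, rnorm(240, 0, 0.4))
  block <- 100:126
  vals[block] <- vals[block] + 1.5
  prof <- make_profile(vals)
  params <- peak_params()
  win <- scan_windows(prof, params)
  expect_true(which.max(win$score) %in% block)
  peaks <- call_peaks(win, params)
  expect_gte(nrow(peaks), 1)
  top <- peaks[which.max(peaks$peakscore), ]
  expect_lt(top$start, prof$start[max(block)])
  expect_gt(top$end, prof$start[min(block)])
  expect_true(validate_peaks(peaks, win, params))
  # covering-window significance spreads membership but also forms the peak
  params_cov <- peak_params(significance = "cover")
  peaks_cov <- call_peaks(win, params_cov)
  expect_gte(nrow(peaks_cov), 1)
  expect_gte(max(peaks_cov$probe_count), max(peaks$probe_count))
  expect_true(validate_peaks(peaks_cov, win, params_cov))
})

test_that("min-probes and max-spacing rules decide peak formation", {
  params <- peak_params()

  # two significant probes 400 bp apart: one peak of 2 probes
  prof <- hot_profile(c(60000, 60400))
  win <- scan_windows(prof, params)
  expect_true(all(win$n_probes == 1L))
  peaks <- call_peaks(win, params)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$probe_count, 2L)
  expect_true(validate_peaks(peaks, win, params))

  # same two probes 600 bp apart: runs of one probe each, no peaks
  win600 <- scan_windows(hot_profile(c(60000, 60600)), params)
  expect_equal(sum(win600$score >= 2), 2)  # both hot probes significant
  expect_equal(nrow(call_peaks(win600, params)), 0)

  # one isolated significant probe: no peak
  win1 <- scan_windows(hot_profile(60000), params)
  expect_gte(sum(win1$score >= 2), 1)
  expect_equal(nrow(call_peaks(win1, params)), 0)

  # empty input
  expect_equal(nrow(call_peaks(win600[0, ], params)), 0)
})
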