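# Sliding-window one-sided Kolmogorov-Smirnov peak calling.
#
# One window is centered at every probe and spans window_width bp. The window
# probes are tested for being stochastically GREATER than the array-wide
# background (all other probes); a window's score is -log10(p). Probes covered
# by any window at or above the score cutoff are "significant"; maximal runs
# of significant probes with inter-probe gaps <= max_probe_spacing and at
# least min_probes_per_peak members become peaks, scored by the best
# constituent window.

#' Peak-calling parameters
#'
#' Defaults follow the array study's peak-finder settings: sliding window
#' width 750 bp; minimal probes per peak 2; -log10(p) cutoff 2; maximum
#' spacing between nearby probes within a peak 500 bp.
#'
#' @param window_width Window span in bp (centered on each probe).
#' @param min_probes_per_peak Minimum probes in an emitted peak.
#' @param score_cutoff Minimum window score (-log10 p) for significance.
#' @param max_probe_spacing Maximum distance in bp between consecutive
#'   probes within one peak.
#' @param max_exact_combinations Cap on the number of window/background
#'   assignments enumerated for an exact permutation p-value; beyond it the
#'   one-sided asymptotic tail is used.
#' @param significance How a probe earns significance: `"center"` (default;
#'   a probe is significant when the window centered on it reaches the
#'   cutoff, the NimbleScan-style per-probe score) or `"cover"` (a probe is
#'   significant when any window covering it reaches the cutoff, which
#'   spreads one extreme window over all its members and so inflates
#'   single-window events into multi-probe peaks).
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(window_width = 750,
                        min_probes_per_peak = 2L,
                        score_cutoff = 2,
                        max_probe_spacing = 500,
                        max_exact_combinations = 1e5,
                        significance = c("center", "cover")) {
  significance <- match.arg(significance)
  assert_scalar_number(window_width, "window_width", lower = 1)
  assert_scalar_number(min_probes_per_peak, "min_probes_per_peak", lower = 1)
  assert_scalar_number(score_cutoff, "score_cutoff", lower = 0)
  assert_scalar_number(max_probe_spacing, "max_probe_spacing", lower = 1)
  assert_scalar_number(max_exact_combinations, "max_exact_combinations",
                       lower = 1)
  structure(list(
    window_width = window_width,
    min_probes_per_peak = as.integer(min_probes_per_peak),
    score_cutoff = score_cutoff,
    max_probe_spacing = max_probe_spacing,
    max_exact_combinations = max_exact_combinations,
    significance = significance
  ), class = "peak_params")
}

# One-sided D+ statistic: sup_x [ECDF_bg(x) - ECDF_window(x)], clipped to
# [0, 1]. Both ECDFs are right-continuous with ties sharing steps; the
# supremum is attained approaching a window jump point from below, so it is
# evaluated with strict "less than" counts at each window value.
ks_dplus <- function(window_values, background_values) {
  w <- sort(window_values)
  m <- length(w)
  n <- length(background_values)
  cb <- findInterval(w, sort(background_values), left.open = TRUE)
  cw <- findInterval(w, w, left.open = TRUE)
  max(c(0, cb / n - cw / m))
}

ks_exact_feasible <- function(m, n, max_comb) {
  k <- min(m, n)
  if (k > 8) return(FALSE)
  ncomb <- choose(m + n, k)
  is.finite(ncomb) && ncomb <= max_comb && ncomb * (m + n) <= 5e6
}

#' One-sided two-sample Kolmogorov-Smirnov test (greater)
#'
#' Tests whether the window values are stochastically greater than the
#' background values. The statistic is
#' `D = sup_x [ECDF_bg(x) - ECDF_win(x)]` clipped to \[0, 1\]; a window
#' entirely below the background yields D = 0 and p = 1. The p-value is
#' computed by exhaustive enumeration of all window/background assignments of
#' the pooled values when `min(m, n) <= 8` and the enumeration is feasible
#' (at most `max_exact_combinations` assignments), and otherwise by the
#' one-sided asymptotic tail `exp(-2 D^2 m n / (m + n))`, which by the
#' one-sided Dvoretzky-Kiefer-Wolfowitz bound never understates the null
#' tail. The permutation null shares the tie convention of the statistic.
#'
#' @param window_values Numeric, non-empty.
#' @param background_values Numeric, at least 2 values.
#' @param max_exact_combinations See [peak_params()].
#' @return List with `d_statistic`, `p_value` (clipped to (1e-300, 1\]),
#'   `score` (-log10 p) and `method` ("exact" or "asymptotic").
#' @export
ks_one_sided <- function(window_values, background_values,
                         max_exact_combinations = 1e5) {
  if (length(window_values) == 0L) {
    stop("window_values must be non-empty", call. = FALSE)
  }
  if (length(background_values) < 2L) {
    stop("background_values needs at least 2 values", call. = FALSE)
  }
  stopifnot(all(is.finite(window_values)), all(is.finite(background_values)))
  m <- length(window_values)
  n <- length(background_values)
  d <- ks_dplus(window_values, background_values)
  if (ks_exact_feasible(m, n, max_exact_combinations)) {
    pooled <- c(window_values, background_values)
    idx <- utils::combn(m + n, m)
    dperm <- apply(idx, 2L, function(i) ks_dplus(pooled[i], pooled[-i]))
    p <- mean(dperm >= d - 1e-12)
    method <- "exact"
  } else {
    p <- exp(-2 * d^2 * m * n / (m + n))
    method <- "asymptotic"
  }
  p <- min(max(p, 1e-300), 1)
  list(d_statistic = d, p_value = p, score = -log10(p), method = method)
}

#' Scan a profile with probe-centered sliding windows
#'
#' Centers one window of `window_width` bp at every probe (probe midpoint);
#' window membership is every probe whose midpoint lies within half a window
#' width of the center. The background for each window is all other probes on
#' the array. Scores are computed by the same statistic as [ks_one_sided()];
#' the exact permutation path is taken per window under the same feasibility
#' rule (it only arises on small profiles or single-probe windows).
#'
#' @param profile A (normalized) `array_profile` with at least 10 probes;
#'   fewer probes cannot define a meaningful array-wide null.
#' @param params A [peak_params()].
#' @return A data frame with one row per probe-centered window: `probe_id`,
#'   `chrom`, `probe_start`, `probe_end`, `center`, `window_start`,
#'   `window_end`, `n_probes`, `d_statistic`, `p_value`, `score`, and the
#'   member-probe row range `first_probe`/`last_probe` (indices into the
#'   profile row order).
#' @export
scan_windows <- function(profile, params = peak_params()) {
  N <- nrow(profile)
  if (N < 10L) {
    stop("profile has fewer than 10 probes; background too small to define a null",
         call. = FALSE)
  }
  hw <- params$window_width / 2
  val <- profile$value
  pos <- (profile$start + profile$end) / 2
  vs <- sort(val)
  d_out <- numeric(N)
  p_out <- numeric(N)
  m_out <- integer(N)
  first_out <- integer(N)
  last_out <- integer(N)
  chrom_groups <- split(seq_len(N), profile$chrom)
  for (g in chrom_groups) {
    p_c <- pos[g]
    v_c <- val[g]
    lo <- findInterval(p_c - hw, p_c, left.open = TRUE) + 1L
    hi <- findInterval(p_c + hw, p_c)
    for (k in seq_along(g)) {
      i <- g[k]
      w <- v_c[lo[k]:hi[k]]
      m <- length(w)
      nbg <- N - m
      if (ks_exact_feasible(m, nbg, params$max_exact_combinations)) {
        res <- ks_one_sided(w, val[-(g[lo[k]]:g[hi[k]])],
                            params$max_exact_combinations)
        d <- res$d_statistic
        p <- res$p_value
      } else {
        if (m > 1L) w <- sort.int(w)
        cb <- findInterval(w, vs, left.open = TRUE)
        cw <- findInterval(w, w, left.open = TRUE)
        d <- max(c(0, (cb - cw) / nbg - cw / m))
        p <- exp(-2 * d^2 * m * nbg / (m + nbg))
        p <- min(max(p, 1e-300), 1)
      }
      d_out[i] <- d
      p_out[i] <- p
      m_out[i] <- m
      first_out[i] <- g[lo[k]]
      last_out[i] <- g[hi[k]]
    }
  }
  out <- data.frame(
    probe_id = profile$probe_id,
    chrom = profile$chrom,
    probe_start = profile$start,
    probe_end = profile$end,
    center = pos,
    window_start = pos - hw,
    window_end = pos + hw,
    n_probes = m_out,
    d_statistic = d_out,
    p_value = p_out,
    score = -log10(p_out),
    first_probe = first_out,
    last_probe = last_out,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  attr(out, "condition") <- attr(profile, "condition")
  out
}

significant_probes <- function(windows, params) {
  sig <- logical(nrow(windows))
  hits <- which(windows$score >= params$score_cutoff)
  if (identical(params$significance, "cover")) {
    for (i in hits) sig[windows$first_probe[i]:windows$last_probe[i]] <- TRUE
  } else {
    sig[hits] <- TRUE
  }
  sig
}

#' Call peaks from window scores
#'
#' Each probe carries the score of the window centered on it; probes at or
#' above `score_cutoff` are significant (with
#' `significance = "cover"`, probes covered by any window above the cutoff
#' are too). Maximal runs of significant probes whose consecutive
#' midpoints are at most `max_probe_spacing` bp apart (and on one
#' chromosome) form candidate peaks; candidates with fewer than
#' `min_probes_per_peak` probes are discarded. A peak spans its first to
#' last member probe (0-based half-open) and its peakscore is the maximum
#' score among windows centered on member probes.
#'
#' @param windows Output of [scan_windows()].
#' @param params A [peak_params()] (should match the scan).
#' @return Data frame of peaks: `chrom`, `start`, `end`, `probe_count`,
#'   `peakscore`, `first_probe`, `last_probe`.
#' @export
call_peaks <- function(windows, params = peak_params()) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), probe_count = integer(),
                      peakscore = numeric(), first_probe = integer(),
                      last_probe = integer(), stringsAsFactors = FALSE)
  if (is.null(windows) || nrow(windows) == 0L) return(empty)
  idx <- which(significant_probes(windows, params))
  if (length(idx) == 0L) return(empty)
  gap_break <- c(TRUE,
                 windows$chrom[idx[-1]] != windows$chrom[idx[-length(idx)]] |
                   diff(windows$center[idx]) > params$max_probe_spacing)
  run_id <- cumsum(gap_break)
  peaks <- lapply(split(idx, run_id), function(members) {
    if (length(members) < params$min_probes_per_peak) return(NULL)
    score <- max(windows$score[members])
    if (score < params$score_cutoff) return(NULL)
    data.frame(
      chrom = windows$chrom[members[1]],
      start = windows$probe_start[members[1]],
      end = windows$probe_end[members[length(members)]],
      probe_count = length(members),
      peakscore = score,
      first_probe = members[1],
      last_probe = members[length(members)],
      stringsAsFactors = FALSE
    )
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks)) return(empty)
  rownames(peaks) <- NULL
  peaks
}

#' Validate peak postconditions
#'
#' Asserts, for every emitted peak: probe count at least
#' `min_probes_per_peak`, peakscore at least `score_cutoff`, and consecutive
#' significant member probes at most `max_probe_spacing` bp apart. Stops
#' with a descriptive error on the first violation.
#'
#' @param peaks Output of [call_peaks()].
#' @param windows The [scan_windows()] output the peaks came from.
#' @param params The [peak_params()] used.
#' @return Invisibly TRUE.
#' @export
validate_peaks <- function(peaks, windows, params = peak_params()) {
  if (nrow(peaks) == 0L) return(invisible(TRUE))
  sig_probe <- significant_probes(windows, params)
  for (r in seq_len(nrow(peaks))) {
    members <- seq.int(peaks$first_probe[r], peaks$last_probe[r])
    members <- members[sig_probe[members]]
    if (length(members) != peaks$probe_count[r]) {
      stop(sprintf("peak %d: probe_count %d != %d significant members",
                   r, peaks$probe_count[r], length(members)), call. = FALSE)
    }
    if (peaks$probe_count[r] < params$min_probes_per_peak) {
      stop(sprintf("peak %d: fewer than %d probes", r,
                   params$min_probes_per_peak), call. = FALSE)
    }
    if (peaks$peakscore[r] < params$score_cutoff) {
      stop(sprintf("peak %d: peakscore below cutoff", r), call. = FALSE)
    }
    if (length(members) > 1L &&
        any(diff(windows$center[members]) > params$max_probe_spacing)) {
      stop(sprintf("peak %d: member probes farther apart than %g bp",
                   r, params$max_probe_spacing), call. = FALSE)
    }
  }
  invisible(TRUE)
}
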