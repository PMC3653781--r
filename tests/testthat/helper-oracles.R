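# Independent reference implementations used as oracles. These deliberately
# share no code with the package: D+ is evaluated pointwise from the ECDF
# definition, the hypergeometric tail is summed from binomial coefficients,
# and BH is the textbook step-up recursion.

oracle_dplus <- function(w, b) {
  xs <- sort(unique(c(w, b)))
  gaps <- vapply(xs, function(x) mean(b < x) - mean(w < x), numeric(1))
  max(0, gaps)
}

oracle_perm_p <- function(w, b) {
  pooled <- c(w, b)
  m <- length(w)
  d0 <- oracle_dplus(w, b)
  combs <- utils::combn(length(pooled), m)
  hits <- apply(combs, 2, function(i) {
    oracle_dplus(pooled[i], pooled[-i]) >= d0 - 1e-12
  })
  mean(hits)
}

oracle_hyper_tail <- function(k, K, n, N) {
  i <- seq.int(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

oracle_bh <- function(p) {
  n <- length(p)
  ro <- order(p)
  q <- numeric(n)
  prev <- 1
  for (r in n:1) {
    idx <- ro[r]
    prev <- min(prev, p[idx] * n / r)
    q[idx] <- prev
  }
  q
}

# Fixture for the spacing/min-probes rules: probes 600 bp apart so that every
# 750 bp window holds exactly one probe; "hot" probes with equal extreme
# values are each significant on their own (exact p = 2/220 => score ~2.04).
hot_profile <- function(hot_positions) {
  n <- 220
  pos <- seq(0, by = 600, length.out = n)
  vals <- withr::with_seed(7, rnorm(n))
  hot_idx <- integer(0)
  for (hp in hot_positions) {
    i <- which.min(abs(pos - hp))
    pos[i] <- hp
    hot_idx <- c(hot_idx, i)
  }
  vals[hot_idx] <- 10
  make_profile(vals, positions = sort(pos))
}

# Minimal profile builder for peak-calling fixtures.
make_profile <- function(values, positions = NULL, spacing = 100,
                         chrom = "chrT", probe_len = 50,
                         condition = "Nor") {
  n <- length(values)
  if (is.null(positions)) positions <- seq(0, by = spacing, length.out = n)
  df <- data.frame(
    probe_id = sprintf("p%04d", seq_len(n)),
    chrom = chrom,
    start = as.integer(positions),
    end = as.integer(positions + probe_len),
    value = values,
    stringsAsFactors = FALSE
  )
  cfsmedip:::as_array_profile(df, condition)
}
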