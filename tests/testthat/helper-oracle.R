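# Independent brute-force oracles, written as literal transcriptions of
# the feature and test definitions. Deliberately kept free of any code
# from R/: explicit sums and loops only, so they can certify the
# vectorized implementations.

oracle_stf <- function(x, bins = ceiling(1 + log2(length(x)))) {
  N <- length(x)
  m <- sum(x) / N

  # grouped mode: histogram over [min, max], leftmost modal class on
  # ties, linear interpolation by neighbour count differences
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    mode_v <- lo
  } else {
    cw <- (hi - lo) / bins
    cnt <- integer(bins)
    for (xi in x) {
      b <- floor((xi - lo) / cw) + 1
      if (b > bins) b <- bins
      cnt[b] <- cnt[b] + 1
    }
    mm <- 1
    for (b in seq_len(bins)) if (cnt[b] > cnt[mm]) mm <- b
    dl <- cnt[mm] - (if (mm > 1) cnt[mm - 1] else 0)
    dr <- cnt[mm] - (if (mm < bins) cnt[mm + 1] else 0)
    Lb <- lo + (mm - 1) * cw
    mode_v <- if (dl + dr == 0) Lb + cw / 2 else Lb + cw * dl / (dl + dr)
  }

  va <- sum((x - m)^2) / N
  rms <- sqrt(sum(x^2) / N)
  mean_abs <- sum(abs(x)) / N
  peak <- max(abs(x))
  smr <- (sum(sqrt(abs(x))) / N)^2

  xs <- sort(x)
  med <- if (N %% 2 == 1) xs[(N + 1) / 2] else (xs[N / 2] + xs[N / 2 + 1]) / 2

  c(mode = mode_v,
    mean = m,
    range = max(x) - min(x),
    variance = va,
    std = sqrt(va),
    impulse_factor = peak / mean_abs,
    smr = smr,
    sf_smr = smr / mean_abs,
    rms = rms,
    sf_rms = rms / mean_abs,
    crest_factor = peak / rms,
    latitude_factor = peak / smr,
    skewness = (sum((x - m)^3) / N) / rms^3,
    kurtosis = (sum((x - m)^4) / N) / rms^4,
    moment5 = (sum((x - m)^5) / N) / rms^5,
    moment6 = (sum((x - m)^6) / N) / rms^6,
    median = med)
}

# tie-corrected Kruskal-Wallis H from midranks, chi-square p
oracle_kw <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x, ties.method = "average")
  H0 <- 0
  off <- 0
  for (g in groups) {
    nj <- length(g)
    Rj <- sum(r[off + seq_len(nj)])
    H0 <- H0 + Rj^2 / nj
    off <- off + nj
  }
  H0 <- 12 / (N * (N + 1)) * H0 - 3 * (N + 1)
  tie <- table(x)
  corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H <- H0 / corr
  list(H = H, p = pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# rank (Mann-Whitney) AUC on decision values, SC positive
oracle_auc <- function(decision, labels) {
  pos <- decision[labels == "SC"]
  neg <- decision[labels == "NSC"]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# small stationary cohort helpers used across tests
tiny_profile <- function(rate = 0) {
  subject_profile("S01", baseline_scale = 10, baseline_offset = 50,
                  burst_rate = rate)
}
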