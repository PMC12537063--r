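# Independent oracles, kept free of the code paths they check.

# Brute-force unbanded affine-gap semi-global DP (score only): read
# global, free end gaps on the reference, gap cost open + (L-1)*extend.
affine_score_oracle <- function(read, ref, sc) {
  a <- strsplit(read, NULL)[[1L]]
  b <- strsplit(ref, NULL)[[1L]]
  n <- length(a); m <- length(b); NI <- -1e18
  M <- matrix(NI, n + 1L, m + 1L)
  X <- matrix(NI, n + 1L, m + 1L)
  Y <- matrix(NI, n + 1L, m + 1L)
  M[1L, ] <- 0
  for (i in 2L:(n + 1L)) for (j in 1L:(m + 1L)) {
    X[i, j] <- max(M[i - 1L, j] + sc$gap_open,
                   X[i - 1L, j] + sc$gap_extend,
                   Y[i - 1L, j] + sc$gap_open)
    if (j > 1L) {
      s <- if (a[i - 1L] == b[j - 1L] && a[i - 1L] != "N") sc$match else sc$mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      Y[i, j] <- max(M[i, j - 1L] + sc$gap_open,
                     Y[i, j - 1L] + sc$gap_extend,
                     X[i, j - 1L] + sc$gap_open)
    }
  }
  max(M[n + 1L, ], X[n + 1L, ])
}

# t CDF through the regularized incomplete beta function (no pt()).
t_cdf_beta <- function(t, df) {
  x <- df / (df + t^2)
  tail <- 0.5 * pbeta(x, df / 2, 0.5)
  ifelse(t >= 0, 1 - tail, tail)
}

# Closed-form Welch test evaluated independently of stats::t.test.
welch_oracle <- function(a, b, tails = "two") {
  va <- var(a); vb <- var(b); na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- if (tails == "two") 2 * t_cdf_beta(-abs(t), df) else 1 - t_cdf_beta(t, df)
  list(t = t, df = df, p = p)
}

# Half-width of the normal-approximation binomial interval, percent
# (z = 1.96 for the 95% interval).
binom_margin <- function(p, n, z = 1.96) 100 * z * sqrt(p * (1 - p) / n)
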