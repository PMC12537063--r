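#' Replicate summary: mean and sample standard deviation
#'
#' @param values Numeric vector (one value per biological replicate).
#' @return List with `n`, `mean`, and `sd` (n-1 denominator; `NA` with a
#'   single value).
#' @export
mean_sd <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, !anyNA(values))
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2L) sd(values) else NA_real_)
}

#' Welch unequal-variance t-test
#'
#' Two-sample t-test without pooling variances, with Welch-Satterthwaite
#' fractional degrees of freedom.  One group may have zero variance
#' (small replicate counts make constant groups possible); both groups
#' constant is degenerate and raises an error.  No multiple-testing
#' correction is applied here; see [adjust_p()] for an optional
#' Benjamini-Hochberg pass over a column of p-values.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param tails `"two"` (default) or `"one"`; one-tailed tests use the
#'   alternative mean(a) > mean(b).
#' @return List with `t`, `df`, `p`, `tails`.
#' @export
welch_t_test <- function(a, b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  if (sd(a) == 0 && sd(b) == 0)
    stop("degenerate comparison: both groups have zero variance")
  ht <- t.test(a, b, var.equal = FALSE,
               alternative = if (tails == "one") "greater" else "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, tails = tails)
}

#' @param p Numeric vector of raw p-values.
#' @param method Passed to [stats::p.adjust()]; default `"BH"`.
#' @rdname welch_t_test
#' @export
adjust_p <- function(p, method = "BH") stats::p.adjust(p, method = method)
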