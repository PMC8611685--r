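#' Paired Wilcoxon signed-rank test (exact or normal approximation)
#'
#' Classic Wilcoxon handling: zero differences are discarded before ranking,
#' absolute differences are ranked with mid-ranks for ties, and the
#' statistic `W` is the sum of ranks of positive differences. For `m <= 20`
#' remaining pairs the two-sided p-value is exact — the probability, under
#' the null of sign-symmetric differences, that `W` is at least as far from
#' its mean `S/2` as observed, over all `2^m` equiprobable sign assignments
#' (computed by a characteristic-polynomial convolution, which enumerates
#' the same distribution). For larger `m` a normal approximation with the
#' mid-rank (tie-corrected) variance `sum(r_i^2)/4` and a 0.5 continuity
#' correction is used.
#'
#' @param a,b paired numeric vectors of equal length (differences `a - b`),
#'   or `b` omitted and `a` a 2-column matrix.
#' @param exact_limit largest `m` for which the exact distribution is used
#'   (default 20).
#' @return A list with `statistic` (W), `p_value` (two-sided), `method`
#'   (`"exact"` or `"normal"`), and `m` (pairs after zero removal).
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))  # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_limit = 20L) {
  if (is.null(b)) {
    if (is.matrix(a) && ncol(a) == 2L) { b <- a[, 2L]; a <- a[, 1L] }
    else stop("supply two paired vectors or a 2-column matrix", call. = FALSE)
  }
  if (length(a) != length(b)) stop("paired vectors differ in length", call. = FALSE)
  d <- as.numeric(a) - as.numeric(b)
  if (anyNA(d)) stop("missing values in paired differences", call. = FALSE)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop("degenerate paired sample", call. = FALSE)
  r <- rank(abs(d))                     # mid-ranks for ties
  w <- sum(r[d > 0])
  s <- m * (m + 1) / 2
  if (m <= exact_limit) {
    p <- exact_signed_rank_p(r, w)
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    dev <- w - s / 2
    z <- if (abs(dev) <= 0.5) 0 else (abs(dev) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal"
  }
  list(statistic = w, p_value = p, method = method, m = m)
}

# Exact two-sided tail probability of the signed-rank statistic for ranks r
# (possibly half-integer mid-ranks). Doubled ranks are integers, so the
# distribution over doubled sums is built by convolution; the result is the
# two-sided symmetric tail P(|W - S/2| >= |w - S/2|).
exact_signed_rank_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  s2 <- sum(r2)
  counts <- numeric(s2 + 1L)
  counts[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(s2 + 1L - rk)])
    counts <- counts + shifted
  }
  prob <- counts / sum(counts)
  w2 <- round(2 * w)
  lo <- min(w2, s2 - w2)
  hi <- max(w2, s2 - w2)
  if (lo == hi) return(1)
  sums2 <- 0:s2
  min(1, sum(prob[sums2 <= lo]) + sum(prob[sums2 >= hi]))
}
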