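#' Exact Wilcoxon signed-rank test
#'
#' Zeros are dropped, absolute differences are mid-ranked, and V is the
#' sum of ranks of the positive differences. For n <= `maxExact` the
#' two-sided p-value is exact over all 2^n equiprobable sign assignments
#' (p = 2 * min(tail), capped at 1); the null distribution is accumulated
#' by convolution over the (doubled, hence integer) ranks, which is
#' arithmetic-identical to full enumeration. Larger n falls back to a
#' normal approximation with tie-corrected variance and a notice.
#'
#' @param differences numeric vector of paired differences; at least one
#'   nonzero.
#' @param maxExact largest n for which the exact distribution is used
#'   (default 25).
#' @return an object of class `"htest"` with `statistic` (V), `p.value`,
#'   and `parameter` (n after zero removal).
#' @examples
#' signedRankExact(rep(1, 7))   # V = 28, p = 2/128 ~ 0.02
#' @export
signedRankExact <- function(differences, maxExact = 25) {
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0) stop("test undefined: all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  r2 <- round(2 * r)              # doubled mid-ranks are integers
  v2 <- round(2 * V)
  if (n <= maxExact) {
    tot <- sum(r2)
    # counts[s + 1] = number of sign vectors with doubled rank-sum s
    counts <- c(1, numeric(tot))
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(tot + 1 - ri)])
      counts <- counts + shifted
    }
    pLe <- sum(counts[seq_len(v2 + 1)]) / 2^n
    pGe <- sum(counts[(v2 + 1):(tot + 1)]) / 2^n
    p <- min(1, 2 * min(pLe, pGe))
    method <- "Exact Wilcoxon signed-rank test (sign-assignment enumeration)"
  } else {
    message("signedRankExact: n > ", maxExact,
            ", using normal approximation")
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  structure(list(statistic = c(V = V), parameter = c(n = n),
                 p.value = p, method = method,
                 data.name = deparse(substitute(differences))),
            class = "htest")
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' W is the Mann-Whitney count for sample `a` (rank sum of `a` minus its
#' minimum). Without ties and with n1 + n2 <= `maxExact` the two-sided
#' p-value is exact over all choose(n1 + n2, n1) group labelings
#' (p = 2 * min(tail), capped at 1). Ties, or larger samples, fall back to
#' a normal approximation with tie correction and a notice.
#'
#' @param a,b numeric vectors, both nonempty.
#' @param maxExact largest n1 + n2 enumerated exactly (default 20).
#' @return an `"htest"` with `statistic` (W), `p.value`, and sample sizes.
#' @examples
#' rankSumExact(c(1, 2), c(3, 4))  # W = 0, p = 2/6
#' @export
rankSumExact <- function(a, b, maxExact = 20) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  hasTies <- anyDuplicated(pooled) > 0
  if (!hasTies && n1 + n2 <= maxExact) {
    combs <- utils::combn(n1 + n2, n1)
    ranksAll <- seq_len(n1 + n2)
    Wall <- colSums(matrix(ranksAll[combs], nrow = n1)) -
      n1 * (n1 + 1) / 2
    pLe <- mean(Wall <= W)
    pGe <- mean(Wall >= W)
    p <- min(1, 2 * min(pLe, pGe))
    method <- "Exact Wilcoxon rank-sum test (labeling enumeration)"
  } else {
    if (hasTies)
      message("rankSumExact: ties present, using normal approximation")
    else
      message("rankSumExact: n1 + n2 > ", maxExact,
              ", using normal approximation")
    mu <- n1 * n2 / 2
    N <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    p <- if (sig2 == 0) 1 else
      min(1, 2 * stats::pnorm(-abs((W - mu) / sqrt(sig2))))
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  structure(list(statistic = c(W = W),
                 parameter = c(n1 = n1, n2 = n2),
                 p.value = p, method = method,
                 data.name = paste(deparse(substitute(a)), "vs",
                                   deparse(substitute(b)))),
            class = "htest")
}

#' Chi-square test of independence on a 2 x 2 table
#'
#' Standard Pearson statistic, df = 1; Yates continuity correction is off
#' by default (switchable).
#'
#' @param tab 2 x 2 matrix of nonnegative counts with positive margins.
#' @param correct apply the continuity correction?
#' @return an `"htest"` with `statistic`, `parameter` (df), `p.value`.
#' @examples
#' chisqIndependence2x2(rbind(c(10, 90), c(30, 70)))  # X-squared = 12.5
#' @export
chisqIndependence2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("test undefined: a margin of the 2x2 table is zero")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  structure(list(statistic = c(`X-squared` = stat),
                 parameter = c(df = 1),
                 p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 expected = expected,
                 method = paste0("Pearson chi-square, 2x2",
                                 if (correct) " (continuity-corrected)"),
                 data.name = deparse(substitute(tab))),
            class = "htest")
}
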