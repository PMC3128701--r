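## Nonparametric machinery shared by the mapping and the behavioural
## analyses. The tests report the rank statistic together with the
## normal-deviate z and a two-sided p, matching the U/z/p triples used in
## clinical lesion-mapping reports. Small tie-free samples are handled
## exactly (null permutation distribution); larger or tied samples use the
## tie-corrected normal approximation with continuity correction.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two independent samples. When the pooled size is at most
#' `exactThreshold` and there are no ties, the two-sided p-value comes from
#' the exact null distribution of U; otherwise from the normal
#' approximation with mid-ranks, tie-corrected variance and a 0.5
#' continuity correction.
#'
#' `U` is the Mann-Whitney statistic of the first sample (`a`); `Umin`
#' additionally reports `min(U_a, U_b)`, the convention used by some
#' statistical software.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exactThreshold exact enumeration used when
#'   `length(a) + length(b) <= exactThreshold` and tie-free. Default 12.
#' @return a list with `U`, `Umin`, `z`, `p`, `method`
#'   (`"rank_sum_exact"` or `"rank_sum_normal"`), `n1`, `n2`, `direction`
#'   (sign of median difference a - b).
#' @examples
#' rankSumTest(c(5, 6, 7), c(1, 2, 3, 4))  # U = 12, p = 2/35
#' @export
rankSumTest <- function(a, b, exactThreshold = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("samples contain NA", call. = FALSE)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  Umin <- min(U, n1 * n2 - U)
  ties <- table(pooled)
  tieless <- all(ties == 1L)

  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) {
    cc <- min(abs(U - mu), 0.5) * sign(U - mu)
    (U - mu - cc) / sqrt(sigma2)
  } else 0
  if (tieless && N <= exactThreshold) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    method <- "rank_sum_exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "rank_sum_normal"
  }
  list(U = U, Umin = Umin, z = z, p = min(1, max(p, .Machine$double.xmin)),
       method = method, n1 = n1, n2 = n2,
       direction = sign(stats::median(a) - stats::median(b)))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (standard convention). Tie-free samples of
#' at most `exactThreshold` non-zero differences are evaluated against the
#' exact sign-flip null distribution; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exactThreshold exact distribution used when the number of
#'   non-zero differences is at most this and their magnitudes are untied.
#' @return a list with `W` (sum of positive-difference ranks), `z`, `p`,
#'   `n` (non-zero pairs), `method`.
#' @export
signedRankTest <- function(x, y, exactThreshold = 12L) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = 0, z = 0, p = 1, n = 0L, method = "signed_rank_degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- table(abs(d))
  tieless <- all(ties == 1L)
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) {
    cc <- min(abs(W - mu), 0.5) * sign(W - mu)
    (W - mu - cc) / sqrt(sigma2)
  } else 0
  if (tieless && n <= exactThreshold) {
    p <- 2 * min(stats::psignrank(W, n), 1 - stats::psignrank(W - 1, n))
    method <- "signed_rank_exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "signed_rank_normal"
  }
  list(W = W, z = z, p = min(1, p), n = n, method = method)
}

#' Pearson chi-square test for an r x k contingency table
#'
#' Thin wrapper around [stats::chisq.test()] without Yates continuity
#' correction, with explicit validation of the table.
#'
#' @param tab integer matrix of counts, at least 2 x 2.
#' @return a list with `statistic`, `df`, `p`, `method`.
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2 x 2", call. = FALSE)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero marginal", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), method = "chi_square")
}

#' Spearman rank correlation
#'
#' Rho via mid-ranks with the usual large-sample p approximation. A
#' constant input vector makes rho undefined; it is returned as `NA` with
#' a warning rather than zero.
#'
#' @param x,y numeric vectors of equal length >= 3 (pairs with NA in
#'   either are dropped).
#' @return a list with `rho`, `p`, `n`.
#' @export
spearmanTest <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(res$estimate), p = res$p.value, n = length(x))
}

#' Holm step-down family-wise correction
#'
#' Applies the Bonferroni-Holm step-down procedure at level `alpha` and
#' reports, besides the rejection vector, the effective critical threshold
#' `H`: the Holm critical value `alpha / (m - k + 1)` at the first
#' non-rejected rank `k` — the value a raw p had to undercut at the point
#' the procedure stopped. When every test is rejected `H = alpha`. Because
#' the boundary convention (strict vs non-strict inequality at `H`) is
#' ambiguous in published reports, `largestRejectedP` is also returned.
#'
#' @param p vector of raw p-values in (0, 1].
#' @param alpha family-wise level in (0, 1).
#' @return a list with `m`, `alpha`, `rejected` (logical, input order),
#'   `H`, `largestRejectedP` (NA if none), `adjusted` (Holm-adjusted p).
#' @examples
#' holmCorrect(c(0.001, 0.03, 0.04), 0.05)  # only 0.001 rejected, H = 0.025
#' @export
holmCorrect <- function(p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  m <- length(p)
  if (m == 0L)
    return(list(m = 0L, alpha = alpha, rejected = logical(0), H = alpha,
                largestRejectedP = NA_real_, adjusted = numeric(0)))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(p, method = "holm")
  rejected <- adjusted <= alpha
  ord <- order(p)
  rejSorted <- rejected[ord]
  k <- match(FALSE, rejSorted)            # first non-rejected rank
  H <- if (is.na(k)) alpha else alpha / (m - k + 1)
  largest <- if (any(rejected)) max(p[rejected]) else NA_real_
  list(m = m, alpha = alpha, rejected = rejected, H = H,
       largestRejectedP = largest, adjusted = adjusted)
}
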