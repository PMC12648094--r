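#' Two-sided Fisher exact test for a 2x2 table (minimum-likelihood rule)
#'
#' Computes the exact two-sided p-value for a 2x2 contingency table under the
#' minimum-likelihood convention: conditioning on both margins, the p-value
#' is the sum of hypergeometric probabilities of every table that is as or
#' less probable than the observed one. A relative tolerance of `1e-7` is
#' applied at the tie boundary so that tables whose probabilities are equal
#' up to floating rounding are counted as ties.
#'
#' This is the convention used by most statistical software for the
#' two-sided Fisher test and reproduces published cohort-table p-values such
#' as 1/56 = 0.0179 for the table `[[3,0],[0,5]]`.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = group, columns =
#'   outcome. Alternatively `a` may be a 2x2 matrix and `b`, `c`, `d`
#'   omitted.
#' @return the two-sided p-value, a number in (0, 1].
#' @examples
#' fisher_exact_2x2(3, 0, 0, 5)          # 1/56
#' fisher_exact_2x2(matrix(c(4, 7, 2, 2), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n < 1) stop("all-zero table: Fisher test undefined", call. = FALSE)
  r1 <- a + b            # row-1 margin
  c1 <- a + c            # col-1 margin
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The null distribution is
#' enumerated exactly (all choose(nx+ny, nx) group assignments) when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Two-sided p-values from the exact path follow the doubling
#' convention, capped at 1.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return a list with elements `U` (the U statistic for `x`), `p_value`,
#'   and `exact` (logical, which path was taken).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (n <= 12L && !has_ties) {
    # enumerate every assignment of nx ranks out of n
    sets <- utils::combn(n, nx)
    ranks <- seq_len(n)
    u_all <- colSums(matrix(ranks[sets], nrow = nx)) - nx * (nx + 1) / 2
    p_lo <- mean(u_all <= u)
    p_hi <- mean(u_all >= u)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = u, p_value = p, exact = TRUE))
  }
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_corr)
  if (sigma2 <= 0) return(list(U = u, p_value = 1, exact = FALSE))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `x - y`. Zero differences are
#' dropped before ranking. The exact null distribution is used for up to 25
#' non-zero pairs, computed by convolution over the observed (mid)ranks so
#' it remains exact in the presence of ties among the absolute differences;
#' above that, the normal approximation with tie correction and continuity
#' correction is used. Two-sided exact p-values use the doubling convention,
#' capped at 1.
#'
#' @param x,y paired numeric vectors of equal length, or `y = NULL` to test
#'   `x` as a vector of differences.
#' @return a list with `V` (sum of positive-difference ranks), `p_value`,
#'   `direction` (`"x_higher"`, `"y_higher"` or `"none"`, sign of the median
#'   difference), `n_used` (non-zero pairs) and `exact`.
#' @examples
#' wilcoxon_signed_rank(c(10, 20, 30, 25, 18, 22), c(2, 3, 1, 2, 0, 1))
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  med <- if (n == 0) 0 else stats::median(d)
  direction <- if (med > 0) "x_higher" else if (med < 0) "y_higher" else "none"
  if (n == 0L) {
    return(list(V = 0, p_value = 1, direction = "none", n_used = 0L,
                exact = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    # exact distribution of V by convolution; double ranks so midranks
    # (.5) become integers
    w <- as.integer(round(2 * r))
    total <- sum(w)
    f <- numeric(total + 1L)   # f[s+1] = #assignments with doubled-V = s
    f[1L] <- 1
    for (wi in w) {
      g <- f
      g[(wi + 1L):(total + 1L)] <- g[(wi + 1L):(total + 1L)] +
        f[1L:(total + 1L - wi)]
      f <- g
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_lo <- sum(f[seq_len(v2 + 1L)])
    p_hi <- sum(f[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(V = v, p_value = p, direction = direction, n_used = n,
                exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  list(V = v, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       direction = direction, n_used = n, exact = FALSE)
}
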