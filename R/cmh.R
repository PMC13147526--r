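## Cochran-Mantel-Haenszel statistics on real-valued stratified tables.
## Strata are the experimental replicates; tables are 2 x J (treatment x
## category) with J = 2 for SNPs (REF/ALT) and J = F for founder
## haplotypes.  Cells may be real-valued pseudo-counts: the CMH formulas
## are evaluated on reals throughout.

#' Classical CMH test for 2 x 2 x K tables
#'
#' `statistic = (sum_k (a_k - E_k))^2 / sum_k V_k` with
#' `E_k = n1k m1k / T_k` and `V_k = n1k n2k m1k m2k / (T_k^2 (T_k - 1))`
#' (classical variant) or `/ T_k^3` (`variance = "uncorrected"`, which
#' makes the statistic scale exactly linearly under cell multiplication).
#' No continuity correction.  Strata with a zero row or column margin
#' contribute nothing; if every stratum is degenerate the result is
#' statistic 0, p = 1 with flag `"degenerate"`.
#'
#' @param tables a 2 x 2 x K numeric array (rows = treatment, columns =
#'   category, slices = replicate strata), or a list of K 2 x 2 matrices.
#' @param variance `"classical"` (default, the T-1 denominator) or
#'   `"uncorrected"`.
#' @return list with `statistic`, `df` (1), `p_value`, `flag`.
#' @export
cmh_2x2xK <- function(tables, variance = c("classical", "uncorrected")) {
  variance <- match.arg(variance)
  x <- as_strata_array(tables, J = 2L)
  a <- x[1, 1, ]; b <- x[1, 2, ]; c_ <- x[2, 1, ]; d <- x[2, 2, ]
  T_ <- a + b + c_ + d
  n1 <- a + b; n2 <- c_ + d
  m1 <- a + c_; m2 <- b + d
  ok <- n1 > 0 & n2 > 0 & m1 > 0 & m2 > 0
  if (!any(ok)) {
    return(list(statistic = 0, df = 1L, p_value = 1, flag = "degenerate"))
  }
  E <- n1 * m1 / T_
  denom <- if (variance == "classical") T_^2 * (T_ - 1) else T_^3
  V <- n1 * n2 * m1 * m2 / denom
  num <- sum((a - E)[ok])
  den <- sum(V[ok])
  stat <- if (den > 0) num^2 / den else 0
  list(statistic = stat, df = 1L,
       p_value = max(pchisq(stat, 1, lower.tail = FALSE), 1e-300),
       flag = if (all(ok)) "" else "degenerate_strata_dropped")
}

#' Generalized CMH test for 2 x J x K tables
#'
#' The general-association CMH statistic: with `x_k` the first-row category
#' counts, `E_k = n1k m_k / T_k` and per-stratum covariance
#' `V_k = n1k n2k / (T_k^2 (T_k - 1)) * (T_k diag(m_k) - m_k m_k')`, the
#' statistic is the quadratic form `d' (sum V_k)^{-1} d` over the first
#' `J - 1` categories of `d = sum (x_k - E_k)`, with df = J - 1.  Reduces
#' to [cmh_2x2xK()] when J = 2.  A singular summed covariance falls back to
#' a pseudo-inverse with the effective df reported.
#'
#' @param tables a 2 x J x K numeric array or list of K 2 x J matrices.
#' @param variance `"classical"` or `"uncorrected"` (see [cmh_2x2xK()]).
#' @return list with `statistic`, `df`, `p_value`, `flag`.
#' @export
cmh_general <- function(tables, variance = c("classical", "uncorrected")) {
  variance <- match.arg(variance)
  x <- as_strata_array(tables)
  J <- dim(x)[2]
  K <- dim(x)[3]
  d <- numeric(J)
  V <- matrix(0, J, J)
  used <- 0L
  for (k in seq_len(K)) {
    tab <- x[, , k]
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
    m <- colSums(tab)
    T_ <- n1 + n2
    if (n1 <= 0 || n2 <= 0 || sum(m > 0) < 2L) next
    used <- used + 1L
    d <- d + tab[1, ] - n1 * m / T_
    denom <- if (variance == "classical") T_^2 * (T_ - 1) else T_^3
    V <- V + n1 * n2 / denom * (T_ * diag(m) - tcrossprod(m))
  }
  if (used == 0L) {
    return(list(statistic = 0, df = J - 1L, p_value = 1, flag = "degenerate"))
  }
  dd <- d[-J]
  VV <- V[-J, -J, drop = FALSE]
  sol <- if (rcond(VV) > 1e-10) {
    list(stat = drop(dd %*% solve(VV, dd)), df = J - 1L, flag = "")
  } else NULL
  if (is.null(sol)) {
    pv <- pseudo_inverse(VV)
    sol <- list(stat = drop(dd %*% (pv$inv %*% dd)), df = pv$rank,
                flag = "singular_covariance")
  }
  stat <- max(sol$stat, 0)
  df <- max(sol$df, 1L)
  flag <- paste(c(if (used < K) "degenerate_strata_dropped",
                  if (nzchar(sol$flag)) sol$flag), collapse = ";")
  list(statistic = stat, df = df,
       p_value = max(pchisq(stat, df, lower.tail = FALSE), 1e-300),
       flag = flag)
}

as_strata_array <- function(tables, J = NULL) {
  if (is.list(tables)) {
    K <- length(tables)
    Jt <- ncol(tables[[1L]])
    x <- array(0, dim = c(2L, Jt, K))
    for (k in seq_len(K)) x[, , k] <- tables[[k]]
  } else {
    x <- tables
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  }
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == 2L)
  if (!is.null(J)) stopifnot(dim(x)[2] == J)
  if (any(x < 0)) stop("table cells must be non-negative")
  x
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = sum(keep))
}

## Vectorized classical 2x2xK CMH over many sites at once.
## a,b,c,d are S x K matrices of cells (row1 = control REF/ALT,
## row2 = case REF/ALT per stratum).  Returns statistic vector.
cmh_2x2xK_vec <- function(a, b, c_, d, variance = "classical") {
  T_ <- a + b + c_ + d
  n1 <- a + b; n2 <- c_ + d
  m1 <- a + c_; m2 <- b + d
  ok <- n1 > 0 & n2 > 0 & m1 > 0 & m2 > 0
  E <- ifelse(ok, n1 * m1 / T_, 0)
  denom <- if (variance == "classical") T_^2 * (T_ - 1) else T_^3
  V <- ifelse(ok, n1 * n2 * m1 * m2 / ifelse(denom > 0, denom, 1), 0)
  num <- rowSums(ifelse(ok, a - E, 0))
  den <- rowSums(V)
  ifelse(den > 0, num^2 / den, 0)
}

#' Bonferroni significance threshold on the -log10 p scale
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return `-log10(alpha / n_tests)`.
#' @export
bonferroni <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_tests)
}
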