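## Founder haplotype frequency inference: constrained least squares
## (f >= 0, sum f = 1) on window SNP frequencies against known founder
## states, SNP-frequency imputation from the fitted frequencies, and
## pseudo-count construction.

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||A x - b||_2` subject to `x >= 0`.  Sized for the small
#' systems used here (a handful of founder columns); exact active-set
#' solution at convergence.
#'
#' @param A numeric matrix (m x p).
#' @param b numeric vector (length m).
#' @param tol dual-feasibility tolerance.
#' @return list with `x` (solution) and `rss` (residual sum of squares).
#' @keywords internal
nnls_fit <- function(A, b, tol = 1e-10) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  w <- Atb  # gradient of -0.5*rss at x = 0
  iter <- 0L
  max_iter <- 30L * p
  scale <- max(abs(Atb), 1)
  while (any(!passive & w > tol * scale) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(replace(w, passive, -Inf))
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      P <- which(passive)
      z[P] <- solve(AtA[P, P, drop = FALSE] +
                      diag(1e-12 * max(diag(AtA)), length(P)),
                    Atb[P])
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg] + 1e-300))
      x <- x + alpha * (z - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- Atb - drop(AtA %*% x)
  }
  list(x = x, rss = sum((drop(A %*% x) - b)^2))
}

#' Constrained least squares on the probability simplex
#'
#' Solves `min ||H f - y||_2` subject to `f >= 0`, `sum(f) = 1` — the
#' window estimator of founder haplotype frequencies from pooled SNP
#' frequencies.  The equality constraint is imposed by augmenting the
#' design with a heavily weighted sum row inside a non-negative
#' least-squares solve, then renormalizing; the result is verified against
#' a simplex grid/vertex oracle in the test suite.
#'
#' @param H numeric matrix (sites x founders), typically 0/1 founder states.
#' @param y observed pooled frequencies (length nrow(H), in \[0, 1\]).
#' @param sum_weight weight on the sum-to-one row of the warm-start NNLS.
#' @return list with `f` (simplex vector), `rss` (residual sum of squares
#'   of `H f - y`), `residual_norm`.
#' @export
lsei_simplex <- function(H, y, sum_weight = 1e4) {
  H <- base::as.matrix(H)
  storage.mode(H) <- "double"
  p <- ncol(H)
  if (p == 1L) {
    f <- 1
  } else {
    AtA <- crossprod(H)
    Atb <- drop(crossprod(H, y))
    scale <- max(abs(Atb), 1)
    # warm start: heavily weighted sum-to-one row inside plain NNLS gives
    # the right active set cheaply
    f0 <- nnls_fit(rbind(H, rep(sum_weight, p)), c(y, sum_weight))$x
    P <- f0 > 1e-8
    if (!any(P)) P <- rep(TRUE, p)
    f <- numeric(p)
    lambda <- 0
    # exact KKT active-set refinement of min ||Hf-y|| s.t. sum f = 1, f >= 0
    for (iter in seq_len(50L * p)) {
      idx <- which(P)
      k <- length(idx)
      K <- rbind(cbind(AtA[idx, idx, drop = FALSE], rep(1, k)),
                 c(rep(1, k), 0))
      rhs <- c(Atb[idx], 1)
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (is.null(sol)) {  # rank-deficient support: minimum-norm minimizer
        sol <- solve(K + diag(1e-10 * max(diag(K), 1), k + 1L), rhs)
      }
      f <- numeric(p)
      f[idx] <- sol[seq_len(k)]
      lambda <- sol[k + 1L]
      if (any(f[idx] < -1e-12)) {
        drop_j <- idx[which.min(f[idx])]
        P[drop_j] <- FALSE
        if (!any(P)) { P[drop_j] <- TRUE; f[f < 0] <- 0; break }
        next
      }
      # dual feasibility for the zeroed founders: mu_j = g_j + lambda >= 0
      mu <- drop(AtA %*% f) - Atb + lambda
      viol <- which(!P & mu < -1e-10 * scale)
      if (length(viol) == 0L) break
      P[viol[which.min(mu[viol])]] <- TRUE
    }
    f[f < 0] <- 0
    s <- sum(f)
    f <- if (s <= 0) rep(1 / p, p) else f / s
  }
  r <- drop(H %*% f) - y
  list(f = f, rss = sum(r^2), residual_norm = sqrt(sum(r^2)))
}

#' Estimate founder frequencies in one window
#'
#' Fits `f = argmin ||H f - y||` on the simplex.  Founders with identical
#' in-window states are indistinguishable; their columns are collapsed for
#' the fit, the fitted group frequency is split equally among the members,
#' and the window is flagged `"non_identifiable"`.  Sites with any missing
#' founder state are excluded.  Windows with fewer usable sites than
#' founders are flagged `"few_sites"`.
#'
#' @param H window founder matrix (sites x F, 0/1/NA).
#' @param y observed pooled SNP frequencies (length nrow(H)).
#' @return list with `f` (length-F simplex vector), `rss`,
#'   `residual_norm`, `flag` ("" when clean).
#' @export
estimate_founder_freqs <- function(H, y) {
  H <- base::as.matrix(H)
  n_founders <- ncol(H)
  ok <- !apply(H, 1L, anyNA) & !is.na(y)
  H <- H[ok, , drop = FALSE]
  y <- y[ok]
  if (nrow(H) == 0L) stop("window has no usable sites")
  stopifnot(all(y >= 0 & y <= 1))
  key <- apply(H, 2L, paste, collapse = "")
  grp <- match(key, unique(key))
  n_grp <- max(grp)
  flags <- character(0)
  if (n_grp < n_founders) flags <- c(flags, "non_identifiable")
  if (nrow(H) < n_founders) flags <- c(flags, "few_sites")
  U <- H[, match(unique(key), key), drop = FALSE]
  fit <- lsei_simplex(U, y)
  size <- tabulate(grp, n_grp)
  f <- fit$f[grp] / size[grp]
  list(f = f, rss = fit$rss, residual_norm = fit$residual_norm,
       flag = paste(flags, collapse = ";"))
}

#' Define sliding genetic-map windows
#'
#' Window centers on a regular cM grid per chromosome (step `step_cM`,
#' full width `width_cM`), spanning the panel's site range so that every
#' site falls in at least one window.
#'
#' @param map a [genetic_map()] (used for chromosome bookkeeping).
#' @param panel a [founder_panel()].
#' @param width_cM full window width in cM (default 1.5).
#' @param step_cM center spacing in cM (default 0.25; must be <= width).
#' @return data.frame of class `scan_windows` with columns `chrom`,
#'   `center_cM`, `half_width_cM`, `n_sites`, `flag`, plus a list column
#'   `sites` of member site indices into the panel.
#' @export
define_windows <- function(map, panel, width_cM = 1.5, step_cM = 0.25) {
  stopifnot(width_cM > 0, step_cM > 0, step_cM <= width_cM)
  if (nrow(map) == 0L) stop("empty genetic map")
  half <- width_cM / 2
  n_founders <- length(panel$founder_ids)
  out <- NULL
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    cm <- panel$map_cM[idx]
    lo <- min(cm); hi <- max(cm)
    centers <- seq(lo, hi, by = step_cM)
    if (centers[length(centers)] < hi) centers <- c(centers, hi)
    if (hi - lo <= width_cM) centers <- (lo + hi) / 2  # single spanning window
    members <- lapply(centers, function(cc) {
      idx[cm >= cc - half & cm <= cc + half]
    })
    usable <- vapply(members, function(m) {
      sum(!apply(panel$matrix[m, , drop = FALSE], 1L, anyNA))
    }, integer(1))
    df <- data.frame(chrom = ch, center_cM = centers,
                     half_width_cM = half, n_sites = usable,
                     flag = ifelse(usable < n_founders, "few_sites", ""),
                     stringsAsFactors = FALSE)
    df$sites <- members
    out <- rbind(out, df)
  }
  class(out) <- c("scan_windows", "data.frame")
  out
}

#' Fit founder haplotype frequencies for every sample and window
#'
#' Per pooled sample and window: observed frequencies `y = ALT/(REF+ALT)`
#' at member sites with coverage >= `min_cov` and complete founder states,
#' fitted with [estimate_founder_freqs()].  Fits are independent across
#' samples.
#'
#' @param pools list of [pool_counts()] aligned to the panel sites.
#' @param panel a [founder_panel()].
#' @param windows from [define_windows()].
#' @param min_cov coverage floor for a site to enter a fit (default 10).
#' @return An object of class `haplotype_freq_track`: list with `freqs`
#'   (array W x F x n_samples), `residual_norm` (W x n_samples), `flag`
#'   (W x n_samples character), `windows`, `samples`.
#' @export
fit_haplotype_track <- function(pools, panel, windows, min_cov = 10) {
  W <- nrow(windows)
  n_founders <- length(panel$founder_ids)
  ns <- length(pools)
  freqs <- array(NA_real_, dim = c(W, n_founders, ns))
  resid <- matrix(NA_real_, W, ns)
  flag <- matrix("", W, ns)
  sample_ids <- vapply(pools, `[[`, character(1), "sample_id")
  for (s in seq_len(ns)) {
    p <- pools[[s]]
    cov <- p$ref + p$alt
    y_all <- ifelse(cov > 0, p$alt / cov, NA_real_)
    y_all[cov < min_cov] <- NA_real_
    for (w in seq_len(W)) {
      m <- windows$sites[[w]]
      fit <- estimate_founder_freqs(panel$matrix[m, , drop = FALSE], y_all[m])
      freqs[w, , s] <- fit$f
      resid[w, s] <- fit$residual_norm
      flag[w, s] <- paste(c(if (nzchar(windows$flag[w])) windows$flag[w],
                            if (nzchar(fit$flag)) fit$flag), collapse = ";")
    }
  }
  structure(list(freqs = freqs, residual_norm = resid, flag = flag,
                 windows = windows[c("chrom", "center_cM", "half_width_cM",
                                     "n_sites", "flag")],
                 samples = sample_ids),
            class = "haplotype_freq_track")
}

#' @export
print.haplotype_freq_track <- function(x, ...) {
  cat(sprintf("<haplotype_freq_track> %d windows x %d founders x %d samples\n",
              dim(x$freqs)[1], dim(x$freqs)[2], dim(x$freqs)[3]))
  invisible(x)
}

## nearest window center per site (ties -> lower center)
nearest_window <- function(site_cM, centers) {
  if (length(centers) == 1L) return(rep(1L, length(site_cM)))
  mid <- (centers[-1L] + centers[-length(centers)]) / 2
  findInterval(site_cM, mid, left.open = TRUE) + 1L
}

#' Impute SNP frequencies from founder-frequency estimates
#'
#' Per site, takes the window whose center is nearest on the cM scale
#' (ties to the lower center) and forms
#' `imputed = sum_j f_hat_j * h_ij`; the result is guaranteed to lie in
#' \[0, 1\] because `f_hat` is on the simplex and founder states are 0/1.
#'
#' @param track a `haplotype_freq_track`.
#' @param panel the [founder_panel()].
#' @return matrix S x n_samples of imputed ALT frequencies (column names
#'   are sample ids).
#' @export
impute_snp_freqs <- function(track, panel) {
  H <- panel$matrix
  if (anyNA(H)) stop("imputation requires complete founder states")
  S <- nrow(H)
  ns <- length(track$samples)
  out <- matrix(NA_real_, S, ns, dimnames = list(NULL, track$samples))
  for (ch in unique(panel$chrom)) {
    si <- which(panel$chrom == ch)
    wi <- which(track$windows$chrom == ch)
    if (length(wi) == 0L) stop("no estimated window on chromosome ", ch)
    win <- wi[nearest_window(panel$map_cM[si], track$windows$center_cM[wi])]
    for (s in seq_len(ns)) {
      fmat <- track$freqs[win, , s, drop = FALSE]
      dim(fmat) <- dim(fmat)[1:2]
      out[si, s] <- rowSums(fmat * H[si, , drop = FALSE])
    }
  }
  out
}

#' Convert frequencies to pseudo-counts
#'
#' `ALT = freq * 2 N k`, `REF = (1 - freq) * 2 N k`, kept real-valued.
#' `N` is the number of diploid individuals in the pool and `k` the
#' imputation efficiency factor; with the default `k = 1` the pseudo-counts
#' assume imputation is as good as genotyping every pooled individual,
#' which inflates downstream test statistics by a genome-wide constant
#' (estimated at roughly 30% for window haplotype imputation).
#'
#' @param freqs frequency vector in \[0, 1\].
#' @param N diploid pool size (>= 1).
#' @param k efficiency factor in (0, 1].
#' @return list with `ref` and `alt` numeric vectors (`ref + alt = 2Nk`).
#' @export
to_pseudo_counts <- function(freqs, N, k = 1) {
  stopifnot(N >= 1, k > 0, k <= 1, all(freqs >= 0 & freqs <= 1))
  list(ref = (1 - freqs) * 2 * N * k, alt = freqs * 2 * N * k)
}
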