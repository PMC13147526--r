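## The three genome scans and their comparison: CMH on direct read counts
## per SNP, generalized CMH on founder-haplotype pseudo-counts per window,
## and CMH on imputed-SNP pseudo-counts per site.

## Build per-replicate control/case count matrices (S x K) from pools,
## summing multiple control pools within a replicate.
stack_counts <- function(pools, what = c("ref", "alt")) {
  reps <- sort(unique(vapply(pools, `[[`, integer(1), "replicate")))
  S <- length(pools[[1L]][[what[1L]]])
  out <- list()
  for (tr in c("control", "case")) {
    m_ref <- matrix(0, S, length(reps))
    m_alt <- matrix(0, S, length(reps))
    n_ind <- numeric(length(reps))
    found <- logical(length(reps))
    for (p in pools) {
      if (p$treatment != tr) next
      k <- match(p$replicate, reps)
      if (length(p$ref) != S) stop("site vectors differ across samples")
      m_ref[, k] <- m_ref[, k] + p$ref
      m_alt[, k] <- m_alt[, k] + p$alt
      n_ind[k] <- n_ind[k] + p$n_individuals
      found[k] <- TRUE
    }
    if (!all(found)) {
      stop("every replicate needs at least one ", tr, " pool")
    }
    out[[tr]] <- list(ref = m_ref, alt = m_alt, n_individuals = n_ind)
  }
  out$replicates <- reps
  out
}

#' Direct-SNP CMH scan on observed read counts
#'
#' Per site, the 2 x 2 x K table of observed REF/ALT read counts
#' (control/case x REF/ALT, one stratum per replicate) is tested with the
#' classical CMH statistic.  Replicates with two control pools have their
#' control counts summed within replicate first.
#'
#' @param pools list of [pool_counts()] covering every replicate in both
#'   treatment arms, sites aligned.
#' @param sites optional data.frame with chrom/pos/cM for the output.
#' @param variance CMH variance variant (see [cmh_2x2xK()]).
#' @return a [scan_result()] with `scan_type = "direct_snp"`.
#' @export
scan_direct_snp <- function(pools, sites = NULL,
                            variance = c("classical", "uncorrected")) {
  variance <- match.arg(variance)
  st <- stack_counts(pools)
  stat <- cmh_2x2xK_vec(st$control$ref, st$control$alt,
                        st$case$ref, st$case$alt, variance = variance)
  p <- pchisq(stat, 1, lower.tail = FALSE)
  S <- length(stat)
  scan_result(seq_len(S),
              sites$chrom %||% rep("region", S),
              sites$pos %||% seq_len(S),
              sites$cM %||% rep(NA_real_, S),
              stat, 1L, p, "direct_snp")
}

#' Founder-haplotype CMH scan on imputed frequencies
#'
#' Per window, each sample's fitted founder frequencies are converted to
#' founder pseudo-counts `f_hat * 2 N k` and assembled into a 2 x F x K
#' table per replicate (control/case x founder), tested with the
#' generalized CMH statistic (df = F - 1).  Multiple control pools within a
#' replicate contribute the sum of their pseudo-counts.  Results are
#' indexed by window center on the cM axis.
#'
#' @param track a `haplotype_freq_track` fitted on all samples.
#' @param meta data.frame with `sample_id`, `treatment`, `replicate`,
#'   `n_individuals` for every sample in the track.
#' @param k_efficiency efficiency factor applied to the pseudo-counts.
#' @param variance CMH variance variant.
#' @return a [scan_result()] with `scan_type = "haplotype"`, one row per
#'   window; non-identifiable window flags are carried through.
#' @export
scan_haplotype <- function(track, meta, k_efficiency = 1,
                           variance = c("classical", "uncorrected")) {
  variance <- match.arg(variance)
  idx <- match(track$samples, meta$sample_id)
  if (anyNA(idx)) stop("track samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  reps <- sort(unique(meta$replicate))
  W <- dim(track$freqs)[1]
  n_founders <- dim(track$freqs)[2]
  stat <- numeric(W); df <- integer(W); pv <- numeric(W); fl <- character(W)
  for (w in seq_len(W)) {
    tabs <- array(0, dim = c(2L, n_founders, length(reps)))
    for (s in seq_along(track$samples)) {
      row <- if (meta$treatment[s] == "control") 1L else 2L
      k <- match(meta$replicate[s], reps)
      tabs[row, , k] <- tabs[row, , k] +
        track$freqs[w, , s] * 2 * meta$n_individuals[s] * k_efficiency
    }
    res <- cmh_general(tabs, variance = variance)
    stat[w] <- res$statistic; df[w] <- res$df; pv[w] <- res$p_value
    fl[w] <- paste(c(if (nzchar(track$windows$flag[w])) track$windows$flag[w],
                     if (nzchar(res$flag)) res$flag), collapse = ";")
  }
  out <- scan_result(seq_len(W), track$windows$chrom, NA_real_,
                     track$windows$center_cM, stat, df, pv, "haplotype",
                     flag = fl)
  out$df <- df  # window-specific effective df
  out
}

#' Imputed-SNP CMH scan on pseudo-counts
#'
#' As [scan_direct_snp()], but the per-site 2 x 2 x K tables hold REF/ALT
#' pseudo-counts `freq * 2 N k` built from imputed SNP frequencies instead
#' of observed read counts.
#'
#' @param imputed S x n_samples matrix from [impute_snp_freqs()] (columns
#'   named by sample id).
#' @param meta per-sample metadata (as in [scan_haplotype()]).
#' @param sites optional site coordinate data.frame.
#' @param k_efficiency efficiency factor.
#' @param variance CMH variance variant.
#' @return a [scan_result()] with `scan_type = "imputed_snp"`.
#' @export
scan_imputed_snp <- function(imputed, meta, sites = NULL, k_efficiency = 1,
                             variance = c("classical", "uncorrected")) {
  variance <- match.arg(variance)
  idx <- match(colnames(imputed), meta$sample_id)
  if (anyNA(idx)) stop("imputed-matrix samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  pools <- lapply(seq_len(ncol(imputed)), function(s) {
    pc <- to_pseudo_counts(imputed[, s], meta$n_individuals[s], k_efficiency)
    pool_counts(meta$sample_id[s], meta$treatment[s], meta$replicate[s],
                meta$n_individuals[s], pc$ref, pc$alt)
  })
  out <- scan_direct_snp(pools, sites = sites, variance = variance)
  out$scan_type <- "imputed_snp"
  out
}

#' Compare scans around a known QTL
#'
#' Per scan: the global maximum of -log10 p, the peak within
#' `+/- window_cM` of the QTL, the maximum outside that window
#' (background), the peak-minus-background gap, the number of loci at or
#' above `threshold`, and a cluster score — for each locus at or above the
#' threshold, the number of other such loci within +/- 1 cM, with the
#' median over hits reported (0 when every hit is isolated or there are no
#' hits).
#'
#' @param scans named list of [scan_result()] tables (values on a common
#'   cM axis).
#' @param qtl_cM genetic position of the true QTL.
#' @param window_cM half-width of the QTL window (default 1.5).
#' @param threshold -log10 p hit threshold (default 5).
#' @param cluster_radius_cM radius for the cluster score (default 1).
#' @return data.frame of class `scan_comparison`, one row per scan with
#'   columns `scan`, `global_max`, `argmax_cM`, `qtl_peak`,
#'   `background_max`, `gap`, `n_hits`, `cluster_score`,
#'   `cluster_fraction` (a density-independent companion: the median, over
#'   hits, of the fraction of loci within the radius that are themselves
#'   hits — raw counts are not comparable between window-level and
#'   SNP-level scans whose locus spacings differ), and `qtl_localized`
#'   (is the global argmax within the QTL window).
#' @export
compare_scans <- function(scans, qtl_cM, window_cM = 1.5, threshold = 5,
                          cluster_radius_cM = 1) {
  rows <- lapply(names(scans), function(nm) {
    sc <- scans[[nm]]
    lp <- sc$neg_log10_p
    cm <- sc$cM
    stopifnot(!anyNA(cm))
    in_win <- abs(cm - qtl_cM) <= window_cM
    gmax <- max(lp)
    argmax <- cm[which.max(lp)]
    qtl_peak <- if (any(in_win)) max(lp[in_win]) else NA_real_
    bg <- if (any(!in_win)) max(lp[!in_win]) else NA_real_
    hits <- which(lp >= threshold)
    cluster <- 0
    cluster_frac <- 0
    if (length(hits) > 0) {
      hc <- cm[hits]
      cnt <- vapply(hc, function(x) {
        sum(abs(hc - x) <= cluster_radius_cM) - 1L
      }, integer(1))
      cluster <- stats::median(cnt)
      # density-independent companion: among ALL loci within the radius of
      # a hit, which fraction are themselves hits (comparable across scans
      # with different locus spacings)
      frac <- vapply(hc, function(x) {
        near <- abs(cm - x) <= cluster_radius_cM
        sum(lp[near] >= threshold) / sum(near)
      }, numeric(1))
      cluster_frac <- stats::median(frac)
    }
    data.frame(scan = nm, global_max = gmax, argmax_cM = argmax,
               qtl_peak = qtl_peak, background_max = bg,
               gap = qtl_peak - bg, n_hits = length(hits),
               cluster_score = cluster, cluster_fraction = cluster_frac,
               qtl_localized = abs(argmax - qtl_cM) <= window_cM,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scan_comparison", "data.frame")
  out
}

#' Write a scan result as a Manhattan-ready TSV
#'
#' Columns chrom, pos_bp, cM, statistic, df, p, neg_log10_p, flag with
#' values printed at 10 significant digits (byte-stable across runs).
#'
#' @param scan a [scan_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  df <- data.frame(chrom = scan$chrom, pos_bp = fmt_num(scan$pos_bp),
                   cM = sprintf("%.10g", scan$cM),
                   statistic = sprintf("%.10g", scan$statistic),
                   df = scan$df, p = sprintf("%.10g", scan$p_value),
                   neg_log10_p = sprintf("%.10g", scan$neg_log10_p),
                   flag = scan$flag, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
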