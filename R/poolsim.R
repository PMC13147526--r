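## In-silico pool-seq case-control experiment: expand a neutral panel into
## large case/control pools differing only at one focal SNP, sequence the
## pools with overdispersed coverage, scan with per-SNP chi-square tests,
## and sweep the coverage x effect-size grid to measure power.

#' Expand a panel into a control pool
#'
#' Samples `M` haplotypes (chromosome copies) uniformly with replacement
#' from the panel, instantaneously creating a large base population whose
#' allele frequencies are the panel frequencies plus resampling noise.
#'
#' @param panel a `haplotype_panel`.
#' @param M pool haplotype count (2N of the pooled individuals).
#' @param seed integer seed.
#' @return integer vector of `M` haplotype row indices (a multiset).
#' @export
expand_to_control_pool <- function(panel, M, seed = NULL) {
  stopifnot(M >= 1)
  with_seed(seed, sample.int(nrow(panel$haplotypes), M, replace = TRUE))
}

#' True allele frequencies of a pool
#'
#' Exact bookkeeping: the per-site ALT frequency among the pooled haplotype
#' copies.
#'
#' @param pool integer vector of haplotype indices into `panel`.
#' @param panel a `haplotype_panel`.
#' @return numeric vector of per-site frequencies in \[0, 1\].
#' @export
pool_freqs <- function(pool, panel) {
  w <- tabulate(pool, nbins = nrow(panel$haplotypes))
  as.vector(w %*% panel$haplotypes) / length(pool)
}

#' Choose an intermediate-frequency focal SNP
#'
#' Uniformly random choice among panel sites whose minor allele frequency
#' lies within `focal_maf_range` (default 0.30-0.70, i.e. "intermediate
#' frequency").
#'
#' @param panel a `haplotype_panel`.
#' @param focal_maf_range numeric `(lo, hi)` MAF bounds, `0 < lo < hi`.
#' @param seed integer seed.
#' @return a site (column) index.
#' @export
select_focal_snp <- function(panel, focal_maf_range = c(0.30, 0.70),
                             seed = NULL) {
  stopifnot(length(focal_maf_range) == 2L,
            focal_maf_range[1] > 0, focal_maf_range[1] < focal_maf_range[2])
  p <- panel_freqs(panel)
  maf <- pmin(p, 1 - p)
  ok <- which(maf >= focal_maf_range[1] & maf <= focal_maf_range[2])
  if (length(ok) == 0L) stop("no site with MAF in the focal range")
  with_seed(seed, ok[sample.int(length(ok), 1L)])
}

#' Sample a case pool conditional on a focal-SNP frequency shift
#'
#' Builds a case pool of the same size as the control pool by stratified
#' resampling: the focal ALT count is fixed at
#' `round((p_control +/- delta_p) * M)` exactly, and within each focal
#' allele class haplotypes are drawn uniformly with replacement from that
#' class of the control pool.  Non-focal sites therefore shift only through
#' their linkage with the focal allele (hitchhiking).
#'
#' @param control_pool integer vector from [expand_to_control_pool()].
#' @param panel the `haplotype_panel` the pool indexes into.
#' @param focal_site focal site (column) index.
#' @param delta_p target allele-frequency difference (>= 0).
#' @param direction `"increase"` (default) or `"decrease"` the ALT allele.
#' @param seed integer seed.
#' @return integer vector of `M` haplotype indices (the case pool).
#' @export
sample_case_pool_conditional <- function(control_pool, panel, focal_site,
                                         delta_p,
                                         direction = c("increase", "decrease"),
                                         seed = NULL) {
  direction <- match.arg(direction)
  M <- length(control_pool)
  focal_allele <- panel$haplotypes[control_pool, focal_site]
  alt_members <- control_pool[focal_allele == 1L]
  ref_members <- control_pool[focal_allele == 0L]
  p_ctrl <- length(alt_members) / M
  target <- p_ctrl + if (direction == "increase") delta_p else -delta_p
  if (target < 0 || target > 1) {
    stop(sprintf("target focal frequency %.4f is outside [0, 1]", target))
  }
  n_alt <- round(target * M)
  if (n_alt > 0 && length(alt_members) == 0L) {
    stop("no ALT-carrying haplotypes in the control pool at the focal site")
  }
  if (n_alt < M && length(ref_members) == 0L) {
    stop("no REF-carrying haplotypes in the control pool at the focal site")
  }
  with_seed(seed, {
    case <- c(
      if (n_alt > 0) alt_members[sample.int(length(alt_members), n_alt,
                                            replace = TRUE)],
      if (n_alt < M) ref_members[sample.int(length(ref_members), M - n_alt,
                                            replace = TRUE)])
    sample(case)  # shuffle so pool order carries no information
  })
}

#' Simulate pool-seq read counts at known frequencies
#'
#' Per site, total coverage is drawn from a negative binomial with both
#' `size` and `mu` equal to `expected_coverage` — an overdispersed Poisson
#' with variance twice the mean — and the ALT read count is binomial in the
#' realized coverage at the true pool frequency.  Sites are independent.
#'
#' @param true_freqs per-site true ALT frequencies in \[0, 1\].
#' @param expected_coverage expected sequencing coverage (> 0).
#' @param seed integer seed.
#' @param sample_id,treatment,replicate,n_individuals metadata for the
#'   returned [pool_counts()].
#' @return a [pool_counts()].
#' @export
simulate_poolseq_counts <- function(true_freqs, expected_coverage, seed = NULL,
                                    sample_id = "pool", treatment = "control",
                                    replicate = 1L, n_individuals = 1) {
  stopifnot(expected_coverage > 0, all(true_freqs >= 0 & true_freqs <= 1))
  with_seed(seed, {
    S <- length(true_freqs)
    cov <- rnbinom(S, size = expected_coverage, mu = expected_coverage)
    alt <- rbinom(S, size = cov, prob = true_freqs)
    pool_counts(sample_id, treatment, replicate, n_individuals,
                ref = cov - alt, alt = alt)
  })
}

## Vectorized per-site 2x2 Pearson chi-square on count vectors.
## Rows are REF/ALT, columns case/control; no continuity correction.
## Degenerate tables (a zero row or column margin) get stat 0, p 1.
pearson_chisq_2x2 <- function(a, b, c, d) {
  T_ <- a + b + c + d
  r1 <- a + b; r2 <- c + d
  c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  stat <- ifelse(denom > 0, T_ * (a * d - b * c)^2 / denom, 0)
  stat
}

#' Per-SNP chi-square scan of a case/control pool pair
#'
#' Pearson 2x2 chi-square (REF/ALT x case/control) on the read counts at
#' every site, no continuity correction, df = 1.  Sites with a zero row or
#' column margin (e.g. zero coverage in both pools) are reported with
#' statistic 0 and p = 1 so the site vector stays aligned.
#'
#' @param case,control [pool_counts()] with matched site vectors.
#' @param chrom,pos_bp,cM optional site coordinates for the result table.
#' @return a [scan_result()] data.frame with `scan_type = "direct_snp"`.
#' @export
chisq_scan <- function(case, control, chrom = "region",
                       pos_bp = seq_along(case$ref), cM = NA_real_) {
  if (length(case$ref) != length(control$ref)) {
    stop("case and control site vectors differ in length")
  }
  stat <- pearson_chisq_2x2(control$ref, control$alt, case$ref, case$alt)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  scan_result(seq_along(stat), chrom, pos_bp, cM, stat, 1L, p, "direct_snp")
}

#' Power sweep over the coverage x effect-size grid
#'
#' Repeats the simulated case-control experiment for every combination of
#' expected coverage and focal allele-frequency difference.  Per replicate a
#' control pool of `M` haplotypes is expanded from the panel, a focal SNP is
#' chosen, a case pool is sampled conditional on the focal shift, and both
#' pools are pool-sequenced at each coverage.  Per grid cell the function
#' reports the fraction of replicates in which the focal SNP's -log10 p
#' exceeds `threshold` (power) and the fraction in which any non-focal SNP
#' exceeds it (genome-wide false-signal rate).
#'
#' @param panel a `haplotype_panel` (already MAF-filtered as desired).
#' @param coverages numeric vector of expected coverages.
#' @param delta_ps numeric vector of focal frequency differences (may
#'   include 0 for null calibration).
#' @param n_reps simulation replicates per cell.
#' @param M pool haplotype count (default 10000).
#' @param threshold -log10 p significance threshold (default 5).
#' @param focal_maf_range focal SNP MAF window (default 0.30-0.70).
#' @param seed master seed; per-replicate streams are derived from it.
#' @param keep_scans if `TRUE`, attach the first replicate's per-cell scan
#'   tables (Manhattan-ready) as attribute `"example_scans"`.
#' @return data.frame with one row per (coverage, delta_p) cell: columns
#'   `coverage`, `delta_p`, `n_reps`, `power`, `false_signal_rate`,
#'   `mean_focal_neg_log10_p`.
#' @export
run_power_sweep <- function(panel, coverages = c(400, 1000, 5000),
                            delta_ps = c(0.04, 0.08), n_reps = 50,
                            M = 10000, threshold = 5,
                            focal_maf_range = c(0.30, 0.70), seed = 1,
                            keep_scans = FALSE) {
  cells <- expand.grid(coverage = coverages, delta_p = delta_ps,
                       KEEP.OUT.ATTRS = FALSE)
  example_scans <- list()
  hit_focal <- matrix(0, nrow(cells), n_reps)
  hit_other <- matrix(0, nrow(cells), n_reps)
  focal_lp <- matrix(NA_real_, nrow(cells), n_reps)
  for (rep_i in seq_len(n_reps)) {
    ctrl <- expand_to_control_pool(
      panel, M, seed = derive_stage_seed(seed, "control_pool", rep_i))
    focal <- select_focal_snp(panel, focal_maf_range,
                              seed = derive_stage_seed(seed, "focal", rep_i))
    p_ctrl <- pool_freqs(ctrl, panel)
    for (dp in unique(cells$delta_p)) {
      case <- sample_case_pool_conditional(
        ctrl, panel, focal, dp,
        seed = derive_stage_seed(seed, sprintf("case_%g", dp), rep_i))
      p_case <- pool_freqs(case, panel)
      for (cv in unique(cells$coverage)) {
        row <- which(cells$coverage == cv & cells$delta_p == dp)
        s2 <- derive_stage_seed(seed, sprintf("seq_%g_%g", dp, cv), rep_i)
        ctrl_counts <- simulate_poolseq_counts(p_ctrl, cv, seed = s2,
                                               sample_id = "ctrl")
        case_counts <- simulate_poolseq_counts(p_case, cv, seed = s2 + 1L,
                                               sample_id = "case",
                                               treatment = "case")
        scan <- chisq_scan(case_counts, ctrl_counts,
                           pos_bp = panel$positions_bp)
        lp <- scan$neg_log10_p
        hit_focal[row, rep_i] <- as.numeric(lp[focal] >= threshold)
        hit_other[row, rep_i] <- as.numeric(any(lp[-focal] >= threshold))
        focal_lp[row, rep_i] <- lp[focal]
        if (keep_scans && rep_i == 1L) {
          scan$is_focal <- seq_len(nrow(scan)) == focal
          example_scans[[sprintf("cov%g_dp%g", cv, dp)]] <- scan
        }
      }
    }
  }
  cells$n_reps <- n_reps
  cells$power <- rowMeans(hit_focal)
  cells$false_signal_rate <- rowMeans(hit_other)
  cells$mean_focal_neg_log10_p <- rowMeans(focal_lp)
  if (keep_scans) attr(cells, "example_scans") <- example_scans
  cells
}
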