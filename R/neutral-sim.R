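## Neutral coalescent haplotype panels.  The heavy lifting (coalescent with
## recombination at Drosophila-scale rho) is delegated to msprime through a
## bundled Python helper; everything downstream of the raw 0/1 matrix is
## done here.

#' Simulate a neutral haplotype panel
#'
#' Draws `n` haplotypes from a neutrally evolving panmictic population of
#' diploid effective size `N_e` over a region of `L` bp with per-bp per-
#' generation mutation rate `u` and recombination rate `r`, under the
#' standard coalescent with recombination (msprime backend, infinite-sites
#' binary mutations).  Monomorphic sites are dropped.  Deterministic given
#' `seed`.
#'
#' The default parameters are wild *D. melanogaster*-like:
#' `N_e = 1e6`, `u = 5e-9`, `r = 2e-8`.
#'
#' @param n number of haplotypes (>= 2).
#' @param L region length in bp.
#' @param N_e diploid effective population size (theta = 4 N_e u per bp).
#' @param u per-bp per-generation mutation rate.
#' @param r per-bp per-generation recombination rate.
#' @param seed integer seed (required; passed to msprime).
#' @param max_sites_cap refuse to simulate if the Watterson-expected number
#'   of segregating sites exceeds this cap (guards against runaway theta).
#' @param python python interpreter to use.
#' @return An object of class `haplotype_panel`: list with `haplotypes`
#'   (n x S 0/1 integer matrix), `positions_bp`, `L`, `params`, `seed`.
#' @export
simulate_neutral_haplotypes <- function(n, L, N_e = 1e6, u = 5e-9, r = 2e-8,
                                        seed, max_sites_cap = 2e6,
                                        python = "python") {
  stopifnot(n >= 2, L >= 1, N_e > 0, u >= 0, r >= 0)
  es <- watterson_expected_sites(n, L, N_e, u)
  if (es > max_sites_cap) {
    stop(sprintf(paste0("expected segregating sites %.3g exceeds cap %.3g; ",
                        "scale down N_e, u or L"), es, max_sites_cap))
  }
  script <- system.file("python", "sim_haplotypes.py", package = "poolxqtl",
                        mustWork = TRUE)
  out <- tempfile("hap_panel_")
  on.exit(unlink(out))
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  status <- system2(python,
                    c(shQuote(script), n, sprintf("%.0f", L),
                      sprintf("%.10g", N_e), sprintf("%.10g", u),
                      sprintf("%.10g", r), max(1L, seed %% 2147483646L),
                      shQuote(out)),
                    stdout = FALSE, stderr = "")
  if (status != 0L) stop("msprime backend failed (exit status ", status, ")")
  lines <- readLines(out)
  hdr <- as.numeric(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  S <- hdr[2L]
  if (S == 0) {
    H <- matrix(0L, nrow = n, ncol = 0L)
    pos <- integer(0)
  } else {
    pos <- as.integer(strsplit(lines[2L], " ", fixed = TRUE)[[1L]])
    H <- matrix(0L, nrow = n, ncol = S)
    for (i in seq_len(n)) {
      H[i, ] <- utf8ToInt(lines[2L + i]) - 48L
    }
  }
  haplotype_panel(H, pos, L, params = list(N_e = N_e, u = u, r = r),
                  seed = seed)
}

#' Construct a haplotype panel object
#'
#' @param haplotypes n x S 0/1 matrix (rows are haplotypes).
#' @param positions_bp strictly increasing integer positions.
#' @param L region length in bp.
#' @param params list of population parameters (N_e, u, r), for the record.
#' @param seed seed used, for the record.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, positions_bp, L, params = list(),
                            seed = NA_integer_) {
  H <- base::as.matrix(haplotypes)
  storage.mode(H) <- "integer"
  stopifnot(nrow(H) >= 2, length(positions_bp) == ncol(H))
  if (ncol(H) > 0) {
    stopifnot(all(H %in% c(0L, 1L)))
    if (is.unsorted(positions_bp, strictly = TRUE)) {
      stop("positions must be strictly increasing")
    }
  }
  structure(list(haplotypes = H, positions_bp = as.integer(positions_bp),
                 L = as.numeric(L), params = params, seed = seed),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d segregating sites (%g bp)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$L))
  invisible(x)
}

#' Alternate-allele frequency per site of a panel
#' @param panel a `haplotype_panel`.
#' @return numeric vector of ALT frequencies.
#' @export
panel_freqs <- function(panel) {
  colMeans(panel$haplotypes)
}

#' Watterson expectation for the number of segregating sites
#'
#' `E[S] = 4 N_e u L * sum_{i=1}^{n-1} 1/i`, the closed-form neutral
#' expectation used to sanity-check simulated panels.
#'
#' @inheritParams simulate_neutral_haplotypes
#' @return expected segregating site count (numeric scalar).
#' @export
watterson_expected_sites <- function(n, L, N_e, u) {
  4 * N_e * u * L * sum(1 / seq_len(n - 1))
}

#' Mean pairwise nucleotide diversity per bp of a panel
#'
#' Unbiased estimator `pi = sum_s 2 p q n/(n-1) / L`; under neutrality its
#' expectation is `4 N_e u`.
#'
#' @param panel a `haplotype_panel`.
#' @return numeric scalar.
#' @export
nucleotide_diversity <- function(panel) {
  n <- nrow(panel$haplotypes)
  p <- panel_freqs(panel)
  sum(2 * p * (1 - p) * n / (n - 1)) / panel$L
}

#' Filter a panel to common SNPs (and optionally thin)
#'
#' Retains sites with minor allele frequency >= `maf_min` in the panel;
#' optionally thins uniformly at random down to `max_sites` sites (site
#' order preserved).
#'
#' @param panel a `haplotype_panel`.
#' @param maf_min minimum minor allele frequency in `[0, 0.5)`.
#' @param max_sites optional cap on the number of retained sites.
#' @param seed seed for the thinning draw (only used when thinning).
#' @return a `haplotype_panel` with the surviving sites.
#' @export
subsample_panel <- function(panel, maf_min = 0.05, max_sites = NULL,
                            seed = NULL) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  p <- panel_freqs(panel)
  maf <- pmin(p, 1 - p)
  keep <- which(maf >= maf_min)
  if (length(keep) == 0L) stop("no sites survive the MAF filter")
  if (!is.null(max_sites) && length(keep) > max_sites) {
    keep <- sort(with_seed(seed, sample(keep, max_sites)))
  }
  haplotype_panel(panel$haplotypes[, keep, drop = FALSE],
                  panel$positions_bp[keep], panel$L,
                  params = panel$params, seed = panel$seed)
}

#' Build a founder panel from haplotypes sampled out of a neutral panel
#'
#' Samples `F` distinct haplotypes (rows) from a simulated panel to act as
#' the known founders of a synthetic multiparent population, keeps the sites
#' still segregating among those founders, and attaches genetic-map
#' coordinates by interpolation.
#'
#' @param panel a `haplotype_panel`.
#' @param n_founders number of founders F (default 8, DSPR-like).
#' @param map a [genetic_map()] covering the region (single chromosome).
#' @param chrom chromosome label to assign (must match the map).
#' @param seed seed for the founder draw.
#' @return a [founder_panel()] with random A/C/G/T ref/alt labels.
#' @export
sample_founders <- function(panel, n_founders = 8, map, chrom = "chr1",
                            seed = NULL) {
  n <- nrow(panel$haplotypes)
  stopifnot(n_founders >= 2, n_founders <= n)
  with_seed(seed, {
    idx <- sample(n, n_founders)
    Fm <- t(panel$haplotypes[idx, , drop = FALSE])  # S x F
    ac <- rowSums(Fm)
    keep <- ac > 0 & ac < n_founders
    Fm <- Fm[keep, , drop = FALSE]
    pos <- panel$positions_bp[keep]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    founder_panel(sprintf("F%d", seq_len(n_founders)), chrom, pos, Fm,
                  interpolate_cM(map, chrom, pos), ref = ref, alt = unname(alt))
  })
}
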