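## Synthetic known-founder advanced-intercross (X-QTL) populations: mosaic
## genomes, a planted liability QTL, truncation-selected case pools,
## replicate structure, and pool-seq read counts.  The truth tables
## (founder and SNP frequencies of every pool) are exact bookkeeping, so
## every downstream estimator can be validated against them.

#' Simulate founder-mosaic genomes
#'
#' After G generations of random mating the ancestry of a haploid genome is
#' modeled as a one-shot Poisson breakpoint process on the genetic-map
#' scale: the breakpoint count is Poisson(G x map length in Morgans),
#' breakpoint positions are i.i.d. uniform in cM, and each segment carries
#' an independently, uniformly drawn founder label.  Each individual gets
#' two independent haploid mosaics.
#'
#' @param panel a [founder_panel()] (supplies founder labels; single
#'   chromosome).
#' @param n_individuals number of diploid individuals.
#' @param G number of intercross generations (>= 1).
#' @param map a [genetic_map()] covering the panel's chromosome.
#' @param seed integer seed.
#' @return An object of class `mosaic_pop`: flat segment arrays plus
#'   per-haploid offsets (haploids `2i-1`, `2i` belong to individual `i`).
#' @export
simulate_mosaics <- function(panel, n_individuals, G, map, seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"), G >= 1, n_individuals >= 1)
  chrom <- unique(panel$chrom)
  if (length(chrom) != 1L) stop("mosaic simulation handles one chromosome")
  a <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(a) == 0L) stop("chromosome ", chrom, " not in map")
  if (min(a$pos) > min(panel$pos) || max(a$pos) < max(panel$pos)) {
    stop("genetic map does not span the panel positions")
  }
  lo <- min(a$cM); hi <- max(a$cM)
  n_founders <- length(panel$founder_ids)
  n_individuals <- as.integer(n_individuals)
  n_hap <- 2L * n_individuals
  lambda <- G * (hi - lo) / 100
  with_seed(seed, {
    k <- rpois(n_hap, lambda)
    n_seg <- k + 1L
    total <- sum(n_seg)
    first <- cumsum(c(1L, n_seg[-n_hap]))
    start <- numeric(total)
    start[first] <- lo
    if (sum(k) > 0) {
      u <- runif(sum(k), lo, hi)
      hap_b <- rep.int(seq_len(n_hap), k)
      start[-first] <- u[order(hap_b, u)]
    }
    label <- sample.int(n_founders, total, replace = TRUE)
    last <- first + n_seg - 1L
    end <- c(start[-1L], 0)
    end[last] <- hi + 1e-9  # keep sites at the map end covered
    structure(
      list(chrom = chrom, n_individuals = n_individuals, n_hap = n_hap,
           first = first, n_seg = n_seg, start_cM = start, end_cM = end,
           label = label, founder_ids = panel$founder_ids,
           cM_range = c(lo, hi), G = G),
      class = "mosaic_pop")
  })
}

#' @export
print.mosaic_pop <- function(x, ...) {
  cat(sprintf("<mosaic_pop> %d individuals (%d haploids), %s founders, %.3g segments\n",
              x$n_individuals, x$n_hap, length(x$founder_ids),
              length(x$start_cM)))
  invisible(x)
}

#' Founder label of every haploid at one genetic position
#'
#' @param mos a `mosaic_pop`.
#' @param cM genetic position within the map range.
#' @return integer vector (length `n_hap`) of founder indices.
#' @export
founder_at <- function(mos, cM) {
  stopifnot(cM >= mos$cM_range[1], cM <= mos$cM_range[2])
  cs <- cumsum(mos$start_cM <= cM)
  last <- mos$first + mos$n_seg - 1L
  cnt <- cs[last] - c(0, cs)[mos$first]
  mos$label[mos$first + cnt - 1L]
}

#' Segment list of one haploid genome
#'
#' Materializes one mosaic as an ordered `(start, end, founder)` table, in
#' cM and (if a map is given) in bp via inverse map interpolation.
#'
#' @param mos a `mosaic_pop`.
#' @param hap_id haploid index in `1..n_hap`.
#' @param map optional [genetic_map()] for bp coordinates.
#' @return data.frame with columns `start_cM`, `end_cM`, `founder` (and
#'   `start_bp`, `end_bp` when `map` is supplied).
#' @export
mosaic_segments <- function(mos, hap_id, map = NULL) {
  stopifnot(hap_id >= 1, hap_id <= mos$n_hap)
  rows <- mos$first[hap_id] + seq_len(mos$n_seg[hap_id]) - 1L
  out <- data.frame(start_cM = mos$start_cM[rows],
                    end_cM = pmin(mos$end_cM[rows], mos$cM_range[2]),
                    founder = mos$founder_ids[mos$label[rows]],
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    a <- map[map$chrom == mos$chrom, , drop = FALSE]
    inv <- function(x) approx(a$cM, a$pos, xout = x, ties = "ordered")$y
    out$start_bp <- inv(out$start_cM)
    out$end_bp <- inv(out$end_cM)
  }
  out
}

#' QTL specification
#'
#' A single additive QTL on the liability scale: each founder allele copy
#' at `position_bp` contributes its entry of `founder_effects`, plus
#' Gaussian environmental noise with standard deviation `env_sd`.
#'
#' @param chrom chromosome label.
#' @param position_bp physical position of the causal locus.
#' @param founder_effects numeric vector of per-founder additive effects
#'   (length F; all-zero gives a null locus, useful for calibration).
#' @param env_sd residual (environmental) standard deviation, >= 0.
#' @return object of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, position_bp, founder_effects, env_sd = 1) {
  stopifnot(env_sd >= 0)
  structure(list(chrom = as.character(chrom),
                 position_bp = as.numeric(position_bp),
                 founder_effects = as.numeric(founder_effects),
                 env_sd = as.numeric(env_sd)),
            class = "qtl_spec")
}

#' Assign liability phenotypes
#'
#' Phenotype of individual i = sum of the founder effects carried by its
#' two haploids at the QTL, plus `rnorm(0, env_sd)` noise.
#'
#' @param mos a `mosaic_pop`.
#' @param qtl a [qtl_spec()].
#' @param map a [genetic_map()] (to place the QTL on the cM scale).
#' @param seed integer seed for the environmental noise.
#' @return numeric phenotype vector (length `n_individuals`).
#' @export
assign_phenotypes <- function(mos, qtl, map, seed = NULL) {
  stopifnot(inherits(qtl, "qtl_spec"),
            length(qtl$founder_effects) == length(mos$founder_ids))
  x <- interpolate_cM(map, qtl$chrom, qtl$position_bp)
  lab <- founder_at(mos, x)
  eff <- qtl$founder_effects
  g <- eff[lab[seq(1, mos$n_hap, by = 2)]] + eff[lab[seq(2, mos$n_hap, by = 2)]]
  with_seed(seed, g + rnorm(mos$n_individuals, 0, qtl$env_sd))
}

#' Truncation selection
#'
#' Indices of the `ceiling(q * n)` largest phenotypes; ties are broken by a
#' seeded random permutation.
#'
#' @param phenotypes numeric vector.
#' @param q selected fraction in (0, 1).
#' @param seed integer seed for tie-breaking.
#' @return integer vector of selected indices.
#' @export
truncation_select <- function(phenotypes, q, seed = NULL) {
  stopifnot(q > 0, q < 1)
  n <- length(phenotypes)
  k <- ceiling(q * n - 1e-9)  # guard against 0.07*100 = 7 + 1 ulp
  with_seed(seed, {
    ord <- order(phenotypes, runif(n), decreasing = TRUE)
    ord[seq_len(k)]
  })
}

#' Exact truth tables for a set of pooled individuals
#'
#' Founder-label proportions among the 2N haploids of the pool at every
#' panel site (a simplex vector per site), and the implied true SNP
#' frequencies `snp_freq = sum_j hap_freq_j * h_ij`.  Pure bookkeeping over
#' the mosaic segments; no sampling.
#'
#' @param mos a `mosaic_pop`.
#' @param individuals integer indices of pooled individuals (non-empty).
#' @param panel the [founder_panel()].
#' @return list with `hap_freqs` (S x F matrix, rows on the simplex) and
#'   `snp_freqs` (length-S vector).
#' @export
pool_truth <- function(mos, individuals, panel) {
  stopifnot(length(individuals) > 0)
  haps <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  rows <- sequence(mos$n_seg[haps]) + rep.int(mos$first[haps] - 1L,
                                              mos$n_seg[haps])
  st <- mos$start_cM[rows]
  en <- mos$end_cM[rows]
  lb <- mos$label[rows]
  x <- panel$map_cM
  n_founders <- length(mos$founder_ids)
  counts <- matrix(0L, nrow = length(x), ncol = n_founders)
  for (f in seq_len(n_founders)) {
    i <- lb == f
    counts[, f] <- findInterval(x, sort(st[i])) - findInterval(x, sort(en[i]))
  }
  hap_freqs <- counts / length(haps)
  H <- panel$matrix
  if (anyNA(H)) stop("pool_truth requires a complete founder matrix")
  list(hap_freqs = hap_freqs,
       snp_freqs = rowSums(hap_freqs * H))
}

#' Experiment design for a synthetic X-QTL dataset
#'
#' Defaults mirror the zinc X-QTL design at a runnable scale: K = 12
#' replicates, ~7% truncation selection, per-replicate pool sizes whose
#' totals approximate 4,800 control / 3,420 case individuals, aggregate
#' treatment coverages near 983x (control) and 739x (case), and two
#' equally-sized control pools in replicates 5, 6, 8, 11 and 12.
#'
#' @param K number of replicates.
#' @param n_ctrl,n_case control / case diploid pool sizes per replicate.
#' @param q selected (case) fraction of the phenotyped cohort.
#' @param coverage_ctrl_total,coverage_case_total aggregate expected
#'   coverage per treatment (split evenly across replicate pools).
#' @param k_efficiency imputation efficiency factor in (0, 1] used when
#'   forming pseudo-counts.
#' @param two_control_pool_reps replicate indices that get two separate,
#'   equally sized control pools.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(K = 12, n_ctrl = 400, n_case = 285, q = 0.07,
                              coverage_ctrl_total = 983,
                              coverage_case_total = 739,
                              k_efficiency = 1,
                              two_control_pool_reps = c(5, 6, 8, 11, 12)) {
  stopifnot(K >= 1, n_ctrl >= 1, n_case >= 1, q > 0, q < 1,
            coverage_ctrl_total > 0, coverage_case_total > 0,
            k_efficiency > 0, k_efficiency <= 1,
            all(two_control_pool_reps %in% seq_len(K)))
  structure(list(K = as.integer(K), n_ctrl = n_ctrl, n_case = n_case, q = q,
                 coverage_ctrl_total = coverage_ctrl_total,
                 coverage_case_total = coverage_case_total,
                 k_efficiency = k_efficiency,
                 two_control_pool_reps = as.integer(two_control_pool_reps)),
            class = "experiment_design")
}

#' Generate a complete synthetic X-QTL dataset
#'
#' Per replicate an independent cohort is simulated from the founder panel;
#' `n_ctrl` randomly chosen individuals form the (unselected) control
#' pool(s) and the remaining individuals are phenotyped, with the top
#' `n_case` forming the case pool (`n_case / q` phenotyped individuals are
#' simulated so the selected fraction is `q`).  Each pool is pool-sequenced
#' with [simulate_poolseq_counts()] at its share of the treatment coverage.
#' Exact truth tables are recorded for every pool.
#'
#' @param design an [experiment_design()].
#' @param panel a [founder_panel()].
#' @param qtl a [qtl_spec()].
#' @param map a [genetic_map()].
#' @param G intercross generations (default 33, the midpoint of a 31-36
#'   generation maintenance regime).
#' @param seed master seed; all stage seeds derive from it.
#' @return An object of class `xqtl_dataset`: list with `pools` (list of
#'   [pool_counts()]), `truth` (per-sample truth tables), `sites`, `panel`,
#'   `map`, `design`, `qtl`, `meta` (per-sample metadata data.frame).
#' @export
generate_xqtl_dataset <- function(design, panel, qtl, map, G = 33, seed = 1) {
  stopifnot(inherits(design, "experiment_design"))
  n_pheno <- round(design$n_case / design$q)
  pools <- list()
  truth <- list()
  meta <- NULL
  for (r in seq_len(design$K)) {
    n_cohort <- design$n_ctrl + n_pheno
    mos <- simulate_mosaics(panel, n_cohort, G, map,
                            seed = derive_stage_seed(seed, "mosaics", r))
    ctrl_ids <- with_seed(derive_stage_seed(seed, "ctrl_sample", r),
                          sample.int(n_cohort, design$n_ctrl))
    case_cohort <- setdiff(seq_len(n_cohort), ctrl_ids)
    phen <- assign_phenotypes(mos, qtl, map,
                              seed = derive_stage_seed(seed, "phenotype", r))
    sel <- truncation_select(phen[case_cohort], design$q,
                             seed = derive_stage_seed(seed, "select", r))
    case_ids <- case_cohort[sel][seq_len(min(design$n_case, length(sel)))]
    n_ctrl_pools <- if (r %in% design$two_control_pool_reps) 2L else 1L
    ctrl_split <- split(ctrl_ids,
                        rep(seq_len(n_ctrl_pools),
                            length.out = length(ctrl_ids)))
    cov_ctrl <- design$coverage_ctrl_total / design$K / n_ctrl_pools
    for (j in seq_len(n_ctrl_pools)) {
      sid <- if (n_ctrl_pools == 1L) sprintf("rep%02d_ctrl", r)
             else sprintf("rep%02d_ctrl%d", r, j)
      tr <- pool_truth(mos, ctrl_split[[j]], panel)
      cnt <- simulate_poolseq_counts(
        tr$snp_freqs, cov_ctrl,
        seed = derive_stage_seed(seed, sprintf("seq_ctrl%d", j), r),
        sample_id = sid, treatment = "control", replicate = r,
        n_individuals = length(ctrl_split[[j]]))
      pools[[sid]] <- cnt
      truth[[sid]] <- tr
    }
    sid <- sprintf("rep%02d_case", r)
    tr <- pool_truth(mos, case_ids, panel)
    pools[[sid]] <- simulate_poolseq_counts(
      tr$snp_freqs, design$coverage_case_total / design$K,
      seed = derive_stage_seed(seed, "seq_case", r),
      sample_id = sid, treatment = "case", replicate = r,
      n_individuals = length(case_ids))
    truth[[sid]] <- tr
  }
  meta <- data.frame(
    sample_id = vapply(pools, `[[`, character(1), "sample_id"),
    treatment = vapply(pools, `[[`, character(1), "treatment"),
    replicate = vapply(pools, `[[`, integer(1), "replicate"),
    n_individuals = vapply(pools, `[[`, numeric(1), "n_individuals"),
    row.names = NULL)
  sites <- data.frame(chrom = panel$chrom, pos = panel$pos,
                      ref = panel$ref %||% rep("A", length(panel$pos)),
                      alt = panel$alt %||% rep("T", length(panel$pos)),
                      cM = panel$map_cM, stringsAsFactors = FALSE)
  structure(list(pools = pools, truth = truth, sites = sites, panel = panel,
                 map = map, design = design, qtl = qtl, G = G, seed = seed,
                 meta = meta),
            class = "xqtl_dataset")
}

#' @export
print.xqtl_dataset <- function(x, ...) {
  cat(sprintf("<xqtl_dataset> %d pools (%d replicates), %d sites, QTL at %s:%g\n",
              length(x$pools), x$design$K, nrow(x$sites),
              x$qtl$chrom, x$qtl$position_bp))
  invisible(x)
}
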