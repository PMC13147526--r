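## End-to-end experiment drivers: the pool-seq power sweep and the
## three-scan X-QTL comparison, each a pure function of (config, seed).

#' Configuration for the pool-seq power experiment
#'
#' Defaults are the published design: 500 neutral haplotypes under wild
#' *D. melanogaster* parameters, pools of 10,000 haplotype copies, expected
#' coverages 400/1,000/5,000x, focal shifts of 4% and 8%, and a -log10 p
#' threshold of 5.  `L` defaults to a 100-kb region rather than the 1-Mb
#' original purely for runtime; the per-site power at the focal SNP does
#' not depend on the region length.
#'
#' @param n_haplotypes,L,N_e,u,r coalescent panel parameters.
#' @param maf_min common-SNP filter applied to the panel.
#' @param max_sites optional cap on tested sites (uniform thinning).
#' @param M pool haplotype count.
#' @param coverages,delta_ps the design grid.
#' @param n_reps simulation replicates per grid cell.
#' @param threshold -log10 p significance threshold.
#' @param focal_maf_range focal SNP MAF window.
#' @return a validated config list of class `fig1_config`.
#' @export
fig1_config <- function(n_haplotypes = 500, L = 1e5, N_e = 1e6, u = 5e-9,
                        r = 2e-8, maf_min = 0.05, max_sites = NULL,
                        M = 10000, coverages = c(400, 1000, 5000),
                        delta_ps = c(0.04, 0.08), n_reps = 50,
                        threshold = 5, focal_maf_range = c(0.30, 0.70)) {
  cfg <- list(n_haplotypes = n_haplotypes, L = L, N_e = N_e, u = u, r = r,
              maf_min = maf_min, max_sites = max_sites, M = M,
              coverages = coverages, delta_ps = delta_ps, n_reps = n_reps,
              threshold = threshold, focal_maf_range = focal_maf_range)
  stopifnot(cfg$n_haplotypes >= 2, cfg$M >= 2, all(cfg$coverages > 0),
            all(cfg$delta_ps >= 0), cfg$n_reps >= 1)
  structure(cfg, class = c("fig1_config", "poolxqtl_config"))
}

#' Configuration for the synthetic X-QTL three-scan comparison
#'
#' Defaults give a desk-scale analogue of the zinc X-QTL experiment: 8
#' founders drawn from a neutral panel, a 50-cM chromosome carrying about
#' 20,000 SNPs, 12 replicates with ~4,800 control and ~3,420 case
#' individuals in total, aggregate coverages near 983x/739x, 7% truncation
#' selection, and a single additive QTL at mid-chromosome whose favored
#' founder shifts the case founder frequency by roughly 8 points — the
#' effect-size regime that direct pool-seq at these coverages cannot
#' reliably detect.
#'
#' @param n_founders number of founders (default 8).
#' @param founder_sim coalescent parameters for the founder source panel
#'   (list with n, L, N_e, u, r).
#' @param n_sites cap on panel SNP count (uniform thinning).
#' @param total_cM genetic length of the chromosome.
#' @param G intercross generations.
#' @param design an [experiment_design()].
#' @param qtl_founder index of the favored founder.
#' @param qtl_effect additive effect per favored-founder allele copy
#'   (phenotype units).
#' @param env_sd environmental standard deviation.
#' @param qtl_cM genetic position of the QTL (default mid-chromosome).
#' @param width_cM,step_cM,min_cov haplotype-inference settings.
#' @param threshold -log10 p hit threshold for the comparison report.
#' @return a validated config list of class `xqtl_config`.
#' @export
xqtl_config <- function(n_founders = 8,
                        founder_sim = list(n = 32, L = 4e5, N_e = 1e6,
                                           u = 5e-9, r = 2e-8),
                        n_sites = 20000, total_cM = 50, G = 33,
                        design = experiment_design(),
                        qtl_founder = 1, qtl_effect = 0.4, env_sd = 1,
                        qtl_cM = NULL, width_cM = 1.5, step_cM = 0.25,
                        min_cov = 10, threshold = 5) {
  cfg <- list(n_founders = n_founders, founder_sim = founder_sim,
              n_sites = n_sites, total_cM = total_cM, G = G, design = design,
              qtl_founder = qtl_founder, qtl_effect = qtl_effect,
              env_sd = env_sd, qtl_cM = qtl_cM %||% total_cM / 2,
              width_cM = width_cM, step_cM = step_cM, min_cov = min_cov,
              threshold = threshold)
  stopifnot(cfg$n_founders >= 2, cfg$total_cM > 0, cfg$G >= 1,
            inherits(cfg$design, "experiment_design"),
            cfg$qtl_founder >= 1, cfg$qtl_founder <= cfg$n_founders,
            cfg$qtl_effect != 0)
  structure(cfg, class = c("xqtl_config", "poolxqtl_config"))
}

#' Load a config from JSON
#'
#' Reads a JSON file whose top-level keys are arguments of the matching
#' config constructor; unknown keys are a hard error (silent typos corrupt
#' power studies).  The `design` entry, if present, is passed to
#' [experiment_design()].
#'
#' @param path JSON file.
#' @param kind `"fig1"` or `"xqtl"`.
#' @return a config object.
#' @export
read_config <- function(path, kind = c("fig1", "xqtl")) {
  kind <- match.arg(kind)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctor <- if (kind == "fig1") fig1_config else xqtl_config
  known <- names(formals(ctor))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$design)) {
    dknown <- names(formals(experiment_design))
    dbad <- setdiff(names(raw$design), dknown)
    if (length(dbad)) {
      stop("unknown design key(s): ", paste(dbad, collapse = ", "))
    }
    raw$design <- do.call(experiment_design, raw$design)
  }
  do.call(ctor, raw)
}

#' Run the pool-seq power experiment
#'
#' Simulates the neutral panel, runs the coverage x effect-size power
#' sweep, and (optionally) writes `power_summary.tsv` plus one
#' Manhattan-ready scan TSV per grid cell to `out`.  Deterministic given
#' (`config`, `seed`); rerunning writes byte-identical TSVs.
#'
#' @param config a [fig1_config()].
#' @param seed master seed.
#' @param out optional output directory.
#' @return list with `power` (the summary table), `scans` (first-replicate
#'   scan per cell) and `panel`.
#' @export
run_fig1 <- function(config = fig1_config(), seed = 1, out = NULL) {
  stopifnot(inherits(config, "fig1_config"))
  panel <- simulate_neutral_haplotypes(
    config$n_haplotypes, config$L, config$N_e, config$u, config$r,
    seed = derive_stage_seed(seed, "fig1_panel"))
  panel <- subsample_panel(panel, config$maf_min, config$max_sites,
                           seed = derive_stage_seed(seed, "fig1_thin"))
  power <- run_power_sweep(panel, config$coverages, config$delta_ps,
                           config$n_reps, config$M, config$threshold,
                           config$focal_maf_range,
                           seed = derive_stage_seed(seed, "fig1_sweep"),
                           keep_scans = TRUE)
  scans <- attr(power, "example_scans")
  attr(power, "example_scans") <- NULL
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    pw <- power
    for (cc in c("power", "false_signal_rate", "mean_focal_neg_log10_p")) {
      pw[[cc]] <- sprintf("%.10g", pw[[cc]])
    }
    write.table(pw, file.path(out, "power_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(scans)) {
      write_scan_tsv(scans[[nm]], file.path(out, paste0("scan_", nm, ".tsv")))
    }
  }
  list(power = power, scans = scans, panel = panel)
}

## linear bp <-> cM map over the panel region
linear_map <- function(L, total_cM, chrom = "chr1") {
  genetic_map(chrom, c(1, L), c(0, total_cM))
}

#' Build the default synthetic founder panel and map
#'
#' Simulates the founder source panel, samples the founders, thins to
#' `n_sites`, and attaches a linear genetic map of `total_cM`.
#'
#' @param config an [xqtl_config()].
#' @param seed master seed.
#' @return list with `panel` (a [founder_panel()]) and `map`.
#' @export
build_xqtl_panel <- function(config, seed = 1) {
  fs <- config$founder_sim
  src <- simulate_neutral_haplotypes(
    fs$n, fs$L, fs$N_e, fs$u, fs$r,
    seed = derive_stage_seed(seed, "founder_source"))
  map <- linear_map(fs$L, config$total_cM)
  panel <- sample_founders(src, config$n_founders, map,
                           seed = derive_stage_seed(seed, "founder_pick"))
  S <- length(panel$pos)
  if (!is.null(config$n_sites) && S > config$n_sites) {
    keep <- sort(with_seed(derive_stage_seed(seed, "site_thin"),
                           sample.int(S, config$n_sites)))
    panel <- founder_panel(panel$founder_ids, panel$chrom[keep],
                           panel$pos[keep], panel$matrix[keep, , drop = FALSE],
                           panel$map_cM[keep], ref = panel$ref[keep],
                           alt = panel$alt[keep])
  }
  list(panel = panel, map = map)
}

#' Treatment-level frequency estimates and their errors
#'
#' Aggregates a synthetic dataset to one frequency estimate per treatment
#' and site for each of the two routes — directly ascertained
#' (`sum ALT reads / sum coverage`) and imputed (2N-weighted mean of the
#' per-sample imputed frequencies) — and compares both against the exact
#' 2N-weighted truth.
#'
#' @param dataset an `xqtl_dataset`.
#' @param imputed S x n_samples imputed frequency matrix.
#' @return list with per-treatment RMSEs (`rmse` data.frame) and the
#'   underlying frequency matrices (`truth`, `direct`, `imputed`).
#' @export
frequency_rmse <- function(dataset, imputed) {
  trs <- c("control", "case")
  S <- nrow(dataset$sites)
  truth_m <- direct_m <- imp_m <-
    matrix(NA_real_, S, 2, dimnames = list(NULL, trs))
  for (tr in trs) {
    ids <- dataset$meta$sample_id[dataset$meta$treatment == tr]
    wts <- dataset$meta$n_individuals[match(ids, dataset$meta$sample_id)]
    tru <- sapply(ids, function(s) dataset$truth[[s]]$snp_freqs)
    truth_m[, tr] <- drop(tru %*% wts) / sum(wts)
    alt <- rowSums(sapply(ids, function(s) dataset$pools[[s]]$alt))
    cov <- alt + rowSums(sapply(ids, function(s) dataset$pools[[s]]$ref))
    direct_m[, tr] <- ifelse(cov > 0, alt / cov, NA_real_)
    imp_m[, tr] <- drop(imputed[, ids, drop = FALSE] %*% wts) / sum(wts)
  }
  rmse <- data.frame(
    treatment = trs,
    rmse_direct = sqrt(colMeans((direct_m - truth_m)^2, na.rm = TRUE)),
    rmse_imputed = sqrt(colMeans((imp_m - truth_m)^2)),
    row.names = NULL)
  list(rmse = rmse, truth = truth_m, direct = direct_m, imputed = imp_m)
}

#' Run the three-scan X-QTL comparison
#'
#' Generates the synthetic known-founder dataset, fits founder haplotype
#' frequencies per sample in sliding windows, imputes SNP frequencies,
#' runs the direct-SNP, haplotype and imputed-SNP CMH scans, and reports
#' the scan comparison and the frequency-estimation RMSEs.  Deterministic
#' given (`config`, `seed`).
#'
#' @param config an [xqtl_config()].
#' @param seed master seed.
#' @param out optional output directory for scan/report TSVs.
#' @return list with `scans` (named list of scan tables), `comparison`
#'   (from [compare_scans()]), `rmse` (from [frequency_rmse()]), `dataset`,
#'   `track`, `imputed`, `qtl_cM`.
#' @export
run_xqtl_compare <- function(config = xqtl_config(), seed = 1, out = NULL) {
  stopifnot(inherits(config, "xqtl_config"))
  pm <- build_xqtl_panel(config, seed)
  panel <- pm$panel; map <- pm$map
  effects <- numeric(config$n_founders)
  effects[config$qtl_founder] <- config$qtl_effect
  qtl_bp <- approx(map$cM, map$pos, xout = config$qtl_cM,
                   ties = "ordered")$y
  qtl <- qtl_spec(unique(panel$chrom), qtl_bp, effects, config$env_sd)
  dataset <- generate_xqtl_dataset(config$design, panel, qtl, map,
                                   G = config$G,
                                   seed = derive_stage_seed(seed, "dataset"))
  windows <- define_windows(map, panel, config$width_cM, config$step_cM)
  track <- fit_haplotype_track(dataset$pools, panel, windows,
                               min_cov = config$min_cov)
  imputed <- impute_snp_freqs(track, panel)
  k_eff <- config$design$k_efficiency
  scans <- list(
    direct_snp = scan_direct_snp(dataset$pools, sites = dataset$sites),
    haplotype = scan_haplotype(track, dataset$meta, k_efficiency = k_eff),
    imputed_snp = scan_imputed_snp(imputed, dataset$meta,
                                   sites = dataset$sites,
                                   k_efficiency = k_eff))
  qtl_cM <- config$qtl_cM
  comparison <- compare_scans(scans, qtl_cM, window_cM = config$width_cM,
                              threshold = config$threshold)
  rmse <- frequency_rmse(dataset, imputed)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(scans)) {
      write_scan_tsv(scans[[nm]], file.path(out, paste0("scan_", nm, ".tsv")))
    }
    cmp <- comparison
    for (cc in setdiff(names(cmp), c("scan", "qtl_localized", "n_hits"))) {
      cmp[[cc]] <- sprintf("%.10g", cmp[[cc]])
    }
    write.table(cmp, file.path(out, "comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(rmse$rmse, file.path(out, "frequency_rmse.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(scans = scans, comparison = comparison, rmse = rmse,
       dataset = dataset, track = track, imputed = imputed, qtl_cM = qtl_cM)
}
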