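test_that("mosaic breakpoints follow the Poisson(G x Morgans) model", {
  panel <- toy_founders(n_sites = 20, n_founders = 8, total_cM = 20)
  map <- toy_map(20, 21000)
  G <- 5  # lambda = 5 * 0.2 M = 1 breakpoint per haploid
  mos <- simulate_mosaics(panel, 2000, G, map, seed = 11)
  expect_identical(mos$n_hap, 4000L)
  k <- mos$n_seg - 1L
  lambda <- G * 20 / 100
  expect_lt(abs(mean(k) - lambda), 3 * sqrt(lambda / mos$n_hap))
  # variance consistent with Poisson too
  expect_lt(abs(var(k) / mean(k) - 1), 0.15)

  # determinism
  mos2 <- simulate_mosaics(panel, 2000, G, map, seed = 11)
  expect_identical(mos$start_cM, mos2$start_cM)
  expect_identical(mos$label, mos2$label)
})

test_that("zero map length gives single-segment genomes", {
  panel <- founder_panel(c("F1", "F2"), "chr1", c(10L, 20L),
                         matrix(c(0L, 1L, 1L, 0L), 2), c(0, 0))
  map <- genetic_map("chr1", c(1, 100), c(0, 0))
  mos <- simulate_mosaics(panel, 50, 10, map, seed = 1)
  expect_true(all(mos$n_seg == 1L))
  seg <- mosaic_segments(mos, 1, map)
  expect_identical(nrow(seg), 1L)
})

test_that("founder labels are marginally uniform", {
  panel <- toy_founders(n_sites = 30, n_founders = 8, total_cM = 20)
  map <- toy_map(20, 31000)
  mos <- simulate_mosaics(panel, 2000, 10, map, seed = 5)
  for (x in c(0, 7.3, 20)) {
    lab <- founder_at(mos, x)
    frac <- tabulate(lab, 8) / mos$n_hap
    expect_true(all(abs(frac - 1 / 8) <
                      4 * sqrt((1 / 8) * (7 / 8) / mos$n_hap)))
  }
})

test_that("mosaic segments tile the chromosome", {
  panel <- toy_founders(n_sites = 10, n_founders = 4, total_cM = 15)
  map <- toy_map(15, 11000)
  mos <- simulate_mosaics(panel, 30, 20, map, seed = 2)
  for (h in c(1, 17, 60)) {
    seg <- mosaic_segments(mos, h)
    expect_equal(seg$start_cM[1], 0)
    expect_equal(seg$end_cM[nrow(seg)], 15, tolerance = 1e-6)
    if (nrow(seg) > 1) {
      expect_equal(seg$start_cM[-1], seg$end_cM[-nrow(seg)])
    }
  }
})

test_that("phenotypes are founder-effect sums plus Gaussian noise", {
  panel <- toy_founders(n_sites = 20, n_founders = 4, total_cM = 10)
  map <- toy_map(10, 21000)
  mos <- simulate_mosaics(panel, 5000, 8, map, seed = 3)

  q0 <- qtl_spec("chr1", 10000, c(0, 0, 0, 0), env_sd = 0)
  expect_true(all(assign_phenotypes(mos, q0, map, seed = 1) == 0))

  q1 <- qtl_spec("chr1", 10000, c(1, 0, 0, 0), env_sd = 0)
  ph <- assign_phenotypes(mos, q1, map, seed = 1)
  lab <- founder_at(mos, interpolate_cM(map, "chr1", 10000))
  dosage <- (lab[seq(1, mos$n_hap, 2)] == 1) + (lab[seq(2, mos$n_hap, 2)] == 1)
  expect_identical(ph, as.numeric(dosage))

  # variance decomposition at env_sd = 2
  q2 <- qtl_spec("chr1", 10000, c(1, 0, 0, 0), env_sd = 2)
  ph2 <- assign_phenotypes(mos, q2, map, seed = 9)
  expect_lt(abs(var(ph2) - (var(dosage) + 4)) / (var(dosage) + 4), 0.1)
})

test_that("truncation selection takes the top q fraction", {
  expect_length(truncation_select(rnorm(100), 0.999, seed = 1), 100)
  expect_length(truncation_select(rnorm(100), 0.07, seed = 1), 7)
  sel <- truncation_select(1:10, 0.2, seed = 1)
  expect_setequal(sel, c(9, 10))
  # ties broken by permutation, still correct count
  sel2 <- truncation_select(rep(1, 50), 0.1, seed = 2)
  expect_length(sel2, 5)
})

test_that("pool_truth is exact bookkeeping (dual counting routes agree)", {
  panel <- toy_founders(n_sites = 25, n_founders = 4, total_cM = 12)
  map <- toy_map(12, 26000)
  mos <- simulate_mosaics(panel, 40, 10, map, seed = 6)
  ids <- c(3, 7, 21, 38, 40)
  tr <- pool_truth(mos, ids, panel)
  expect_equal(rowSums(tr$hap_freqs), rep(1, 25))
  expect_true(all(tr$snp_freqs >= 0 & tr$snp_freqs <= 1))
  # independent route: founder_at per site over the pooled haploids
  haps <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  for (s in seq_len(25)) {
    lab <- founder_at(mos, panel$map_cM[s])[haps]
    hf <- tabulate(lab, 4) / length(haps)
    expect_equal(tr$hap_freqs[s, ], hf)
    expect_equal(tr$snp_freqs[s], sum(hf * panel$matrix[s, ]))
  }
})

test_that("single-founder pools give degenerate truth", {
  panel <- toy_founders(n_sites = 12, n_founders = 3, total_cM = 5)
  # hand-build a mosaic population where every segment is founder 2
  mos <- structure(list(chrom = "chr1", n_individuals = 4L, n_hap = 8L,
                        first = seq(1L, 8L), n_seg = rep(1L, 8),
                        start_cM = rep(0, 8), end_cM = rep(5 + 1e-9, 8),
                        label = rep(2L, 8), founder_ids = panel$founder_ids,
                        cM_range = c(0, 5), G = 1),
                   class = "mosaic_pop")
  tr <- pool_truth(mos, 1:4, panel)
  expect_equal(tr$hap_freqs, matrix(rep(c(0, 1, 0), each = 12), 12))
  expect_equal(tr$snp_freqs, as.numeric(panel$matrix[, 2]))
})

test_that("generate_xqtl_dataset has the right structure and null behaviour", {
  fx <- tiny_xqtl()
  ds <- fx$dataset
  # 4 replicates, one with two control pools -> 4 case + 5 control samples
  expect_length(ds$pools, 9)
  expect_identical(sum(ds$meta$treatment == "case"), 4L)
  expect_identical(sum(ds$meta$treatment == "control"), 5L)
  two <- ds$meta[ds$meta$replicate == 2 & ds$meta$treatment == "control", ]
  expect_identical(nrow(two), 2L)
  expect_equal(sum(two$n_individuals), 120)

  # determinism
  ds2 <- generate_xqtl_dataset(fx$design, fx$panel, fx$qtl, fx$map,
                               G = 20, seed = 42)
  expect_identical(ds$pools[["rep03_case"]]$alt, ds2$pools[["rep03_case"]]$alt)

  # null QTL: truth-frequency differences centered at zero
  q0 <- qtl_spec("chr1", 60000, c(0, 0, 0, 0), env_sd = 1)
  ds0 <- generate_xqtl_dataset(fx$design, fx$panel, q0, fx$map, G = 20,
                               seed = 7)
  d <- rowMeans(sapply(1:4, function(r) {
    ds0$truth[[sprintf("rep%02d_case", r)]]$snp_freqs -
      ds0$truth[[sprintf("rep%02d_ctrl%s", r, if (r == 2) "1" else "")]]$snp_freqs
  }))
  expect_lt(abs(mean(d)), 0.02)
})

test_that("a planted QTL enriches the favored founder in cases, decaying in cM", {
  panel <- toy_founders(n_sites = 60, n_founders = 8, total_cM = 40)
  map <- toy_map(40, 61000)
  qtl <- qtl_spec("chr1", 30500, c(1.5, rep(0, 7)), env_sd = 1)  # ~20 cM
  design <- experiment_design(K = 6, n_ctrl = 150, n_case = 150, q = 0.1,
                              coverage_ctrl_total = 600,
                              coverage_case_total = 600,
                              two_control_pool_reps = integer(0))
  ds <- generate_xqtl_dataset(design, panel, qtl, map, G = 15, seed = 13)
  qtl_cM <- interpolate_cM(map, "chr1", 30500)
  f1_case <- rowMeans(sapply(sprintf("rep%02d_case", 1:6),
                             function(s) ds$truth[[s]]$hap_freqs[, 1]))
  dist <- abs(panel$map_cM - qtl_cM)
  near <- f1_case[dist <= 2]
  mid <- f1_case[dist > 8 & dist <= 14]
  far <- f1_case[dist > 16]
  expect_gt(mean(near), 1 / 8 + 0.03)
  expect_gt(mean(near), mean(mid))
  expect_gt(mean(mid), mean(far))
  expect_lt(abs(mean(far) - 1 / 8), 0.04)

  # selection differential grows with effect size
  qtl_small <- qtl_spec("chr1", 30500, c(0.3, rep(0, 7)), env_sd = 1)
  ds_s <- generate_xqtl_dataset(design, panel, qtl_small, map, G = 15,
                                seed = 13)
  f1_small <- rowMeans(sapply(sprintf("rep%02d_case", 1:6),
                              function(s) ds_s$truth[[s]]$hap_freqs[, 1]))
  expect_gt(mean(near), mean(f1_small[dist <= 2]))
})
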