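test_that("control-pool expansion is uniform-with-replacement and seeded", {
  hp <- hand_panel()
  expect_length(expand_to_control_pool(hp, 1, seed = 1), 1)
  expect_identical(expand_to_control_pool(hp, 500, seed = 9),
                   expand_to_control_pool(hp, 500, seed = 9))
  # multinomial check: per-haplotype counts consistent with uniform draws
  M <- 40000
  pool <- expand_to_control_pool(hp, M, seed = 2)
  obs <- tabulate(pool, nbins = 4)
  exp_ <- rep(M / 4, 4)
  gof <- sum((obs - exp_)^2 / exp_)
  expect_lt(gof, qchisq(1 - 1e-6, df = 3))
})

test_that("focal SNP selection respects the MAF window", {
  hp <- hand_panel()  # freqs 0.5, 0.5, 0.25, 0.75, 0.25
  expect_true(select_focal_snp(hp, c(0.49, 0.51), seed = 1) %in% c(1L, 2L))
  expect_error(select_focal_snp(hp, c(0.01, 0.02), seed = 1), "no site")
  for (s in 1:5) {
    i <- select_focal_snp(hp, c(0.3, 0.7), seed = s)
    f <- panel_freqs(hp)[i]
    expect_true(min(f, 1 - f) >= 0.3)
  }
})

test_that("conditional case sampling fixes the focal shift exactly", {
  # two haplotypes differing only at the focal site; p_control = 0.50
  hp <- haplotype_panel(rbind(c(1L, 1L), c(0L, 1L), c(1L, 0L), c(0L, 0L)),
                        c(10L, 20L), 100)
  M <- 10000
  ctrl <- rep(1:4, each = M / 4)  # exactly p = 0.5 at both sites
  case <- sample_case_pool_conditional(ctrl, hp, 1L, 0.08, seed = 3)
  # 0.58 * 10,000 = 5,800 focal ALT copies, exactly
  expect_identical(sum(hp$haplotypes[case, 1L]), 5800L)
  expect_length(case, M)

  case0 <- sample_case_pool_conditional(ctrl, hp, 1L, 0, seed = 4)
  expect_lt(abs(pool_freqs(case0, hp)[1] - 0.5), 1 / M + 1e-12)

  dn <- sample_case_pool_conditional(ctrl, hp, 1L, 0.08,
                                     direction = "decrease", seed = 5)
  expect_identical(sum(hp$haplotypes[dn, 1L]), 4200L)
  expect_error(sample_case_pool_conditional(ctrl, hp, 1L, 0.7, seed = 1),
               "outside")
})

test_that("linked sites hitchhike with the focal shift, unlinked do not", {
  # site 1 = focal; site 2 in perfect LD (identical column); site 3 r2 = 0
  H <- rbind(c(1L, 1L, 1L),
             c(1L, 1L, 0L),
             c(0L, 0L, 1L),
             c(0L, 0L, 0L))
  hp <- haplotype_panel(H, c(10L, 20L, 30L), 100)
  M <- 8000
  ctrl <- rep(1:4, each = M / 4)
  dp <- 0.08
  shifts <- t(vapply(1:40, function(s) {
    case <- sample_case_pool_conditional(ctrl, hp, 1L, dp, seed = s)
    pool_freqs(case, hp) - pool_freqs(ctrl, hp)
  }, numeric(3)))
  # perfect LD: shift equals delta_p exactly in every draw
  expect_true(all(abs(shifts[, 2] - dp) < 1e-12))
  # zero LD: shift 0 in expectation (3 SE band over 40 draws)
  se <- sd(shifts[, 3]) / sqrt(nrow(shifts))
  expect_lt(abs(mean(shifts[, 3])), 3 * se + 1e-12)
})

test_that("pool-seq counts have NB(size = mu) coverage and binomial alleles", {
  z <- simulate_poolseq_counts(rep(0, 100), 50, seed = 1)
  expect_true(all(z$alt == 0))
  o <- simulate_poolseq_counts(rep(1, 100), 50, seed = 2)
  expect_true(all(o$ref == 0))

  pc <- simulate_poolseq_counts(rep(0.3, 2e5), 1000, seed = 3)
  cov <- pc$ref + pc$alt
  expect_lt(abs(var(cov) / mean(cov) - 2), 0.05)
  expect_lt(abs(mean(cov) - 1000) / 1000, 0.01)
  # frequency-estimate error follows binomial sampling: sd ~ sqrt(pq/C)
  phat <- pc$alt / cov
  expect_lt(abs(sd(phat) / sqrt(mean(0.3 * 0.7 / cov)) - 1), 0.03)

  expect_identical(simulate_poolseq_counts(rep(.5, 10), 20, seed = 4)$alt,
                   simulate_poolseq_counts(rep(.5, 10), 20, seed = 4)$alt)
})

test_that("per-SNP chi-square matches the Pearson formula and oracle", {
  mk <- function(ref, alt, tr = "control") {
    pool_counts("x", tr, 1, 10, ref, alt)
  }
  # balanced table -> no association
  s0 <- chisq_scan(mk(10, 10, "case"), mk(10, 10))
  expect_equal(s0$statistic, 0)
  expect_equal(s0$p_value, 1)

  # hand evaluation: [[30,10],[10,30]] -> 80*(900-100)^2/40^4 = 20
  s1 <- chisq_scan(mk(10, 30, "case"), mk(30, 10))
  expect_equal(s1$statistic, 20)
  expect_equal(s1$p_value, pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(abs(s1$p_value - 7.7e-6), 1e-7)

  # agreement with stats::chisq.test on random non-degenerate tables
  set.seed(8)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    sc <- chisq_scan(mk(cells[3], cells[4], "case"), mk(cells[1], cells[2]))
    or <- chisq.test(matrix(cells, 2, byrow = TRUE), correct = FALSE)
    expect_equal(sc$statistic, unname(or$statistic), tolerance = 1e-10)
  }

  # exact linear scaling in the cell multiplier
  s2 <- chisq_scan(mk(70, 210, "case"), mk(210, 70))
  expect_equal(s2$statistic, 7 * 20, tolerance = 1e-12)

  # zero margins -> stat 0, p 1; alignment preserved
  s3 <- chisq_scan(mk(c(0, 5), c(0, 5), "case"), mk(c(0, 1), c(0, 9)))
  expect_equal(s3$statistic[1], 0)
  expect_equal(s3$p_value[1], 1)
  expect_gt(s3$statistic[2], 0)

  expect_error(chisq_scan(mk(1, 1), mk(c(1, 2), c(1, 2))), "differ")
})

test_that("null p-values are approximately uniform (KS on the scaled panel)", {
  ps <- subsample_panel(ks_panel(), 0.05)
  ctrl <- expand_to_control_pool(ps, 10000, seed = 21)
  case <- sample_case_pool_conditional(
    ctrl, ps, select_focal_snp(ps, seed = 22), 0, seed = 23)
  fc <- pool_freqs(ctrl, ps)
  fa <- pool_freqs(case, ps)
  cc <- simulate_poolseq_counts(fc, 400, seed = 24)
  ca <- simulate_poolseq_counts(fa, 400, seed = 25, treatment = "case")
  sc <- chisq_scan(ca, cc)
  keep <- which((cc$ref + cc$alt) >= 200 & (ca$ref + ca$alt) >= 200 &
                  fc > 0.3 & fc < 0.7)
  # space qualifying sites out so the KS independence assumption is fair
  keep <- stride_thin(keep, max(1L, length(keep) %/% 5200L))
  expect_gte(length(keep), 5000)
  ks <- suppressWarnings(ks.test(sc$p_value[keep], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("run_power_sweep is deterministic and null-calibrated", {
  hp <- subsample_panel(ks_panel(), 0.05, max_sites = 2000, seed = 1)
  pw <- run_power_sweep(hp, coverages = c(200), delta_ps = c(0),
                        n_reps = 12, M = 4000, threshold = 5, seed = 77)
  # at -log10 p >= 5 the per-site false-positive rate is ~1e-5; the focal
  # site should essentially never fire under the null
  expect_lte(pw$power, 1 / 12)
  pw2 <- run_power_sweep(hp, coverages = c(200), delta_ps = c(0),
                         n_reps = 12, M = 4000, threshold = 5, seed = 77)
  expect_identical(pw, pw2)
})
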