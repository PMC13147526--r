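test_that("window grids cover every site with the expected multiplicity", {
  panel <- toy_founders(n_sites = 41, n_founders = 4, total_cM = 10)
  map <- toy_map(10, 42000)

  w1 <- define_windows(map, panel, width_cM = 1.5, step_cM = 1.5)
  member <- table(unlist(w1$sites))
  expect_identical(sort(unique(as.integer(names(member)))), 1:41)

  # width 1.5, step 0.5: interior sites fall in 3 windows (uniform map)
  w2 <- define_windows(map, panel, width_cM = 1.5, step_cM = 0.5)
  cm <- panel$map_cM
  interior <- which(cm > 1 & cm < 9)
  counts <- table(factor(unlist(w2$sites), levels = 1:41))
  expect_true(all(counts[interior] %in% c(3L, 4L)))

  # chromosome shorter than the window -> one spanning window
  small <- toy_founders(n_sites = 5, n_founders = 3, total_cM = 1)
  w3 <- define_windows(toy_map(1, 6000), small, 1.5, 0.25)
  expect_identical(nrow(w3), 1L)
  expect_length(w3$sites[[1]], 5L)

  expect_error(define_windows(map, panel, 1.5, 2), "step")
})

test_that("simplex-constrained least squares recovers known mixtures", {
  # F = 1: the simplex is a point
  f1 <- estimate_founder_freqs(matrix(c(1, 0, 1), 3), c(0.2, 0.9, 0.4))
  expect_equal(f1$f, 1)

  # noiseless exact recovery, 8 founders
  set.seed(41)
  for (i in 1:10) {
    repeat {
      H <- matrix(rbinom(40 * 8, 1, 0.5), 40)
      if (qr(H)$rank == 8) break
    }
    f_true <- as.vector(rdirichlet1(1, 8))
    fit <- estimate_founder_freqs(H, as.vector(H %*% f_true))
    expect_lt(max(abs(fit$f - f_true)), 1e-6)
    expect_identical(fit$flag, "")
  }
})

test_that("the 3x2 hand system matches the dense grid oracle", {
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  fit <- estimate_founder_freqs(H, c(0.7, 0.3, 1.0))
  expect_equal(fit$f, c(0.7, 0.3), tolerance = 1e-7)

  y2 <- c(0.8, 0.3, 1.0)
  fit2 <- estimate_founder_freqs(H, y2)
  grid <- simplex_grid_2(1e-3)
  obj <- colSums((H %*% t(grid) - y2)^2)
  best <- grid[which.min(obj), ]
  expect_lt(max(abs(fit2$f - best)), 2e-3)
  expect_lte(lsei_objective(H, y2, fit2$f), min(obj) + 1e-9)
})

test_that("the fitted point beats vertices and 10,000 random simplex points", {
  set.seed(77)
  for (i in 1:8) {
    S_w <- sample(8:40, 1)
    H <- matrix(rbinom(S_w * 8, 1, 0.5), S_w)
    y <- runif(S_w)
    fit <- estimate_founder_freqs(H, y)
    obj_hat <- lsei_objective(H, y, fit$f)
    for (j in 1:8) {
      expect_lte(obj_hat, lsei_objective(H, y, diag(8)[j, ]) + 1e-9)
    }
    P <- rdirichlet1(10000, 8)
    obj_rand <- colSums((H %*% t(P) - y)^2)
    expect_lte(obj_hat, min(obj_rand) + 1e-9)
  }
})

test_that("the simplex contract holds on arbitrary inputs", {
  set.seed(91)
  for (i in 1:200) {
    S_w <- sample(1:30, 1)
    n_founders <- sample(2:8, 1)
    H <- matrix(rbinom(S_w * n_founders, 1, runif(1, 0.2, 0.8)), S_w)
    y <- runif(S_w)
    fit <- estimate_founder_freqs(H, y)
    expect_true(all(fit$f >= -1e-9))
    expect_lt(abs(sum(fit$f) - 1), 1e-6)
  }
})

test_that("indistinguishable founders are split equally and flagged", {
  H <- cbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0))  # founders 1,2 identical
  fit <- estimate_founder_freqs(H, c(0.6, 0.4, 0.6))
  expect_match(fit$flag, "non_identifiable")
  expect_equal(fit$f[1], fit$f[2])
  expect_equal(sum(fit$f[1:2]), 0.6, tolerance = 1e-6)
  expect_equal(fit$f[3], 0.4, tolerance = 1e-6)

  expect_error(estimate_founder_freqs(matrix(NA_real_, 2, 2), c(.1, .2)),
               "no usable sites")
  few <- estimate_founder_freqs(matrix(c(1, 0, 1), 1, 3), 0.5)
  expect_match(few$flag, "few_sites")
})

test_that("SNP imputation is the founder-state inner product", {
  panel <- toy_founders(n_sites = 30, n_founders = 4, seed = 2)
  map <- toy_map(10, 31000)
  windows <- define_windows(map, panel, 1.5, 0.5)
  W <- nrow(windows)

  # degenerate track: every window says founder 3 with certainty
  track <- structure(list(
    freqs = array(rep(c(0, 0, 1, 0), each = W), c(W, 4, 1)),
    residual_norm = matrix(0, W, 1), flag = matrix("", W, 1),
    windows = windows[c("chrom", "center_cM", "half_width_cM", "n_sites",
                        "flag")],
    samples = "s1"), class = "haplotype_freq_track")
  imp <- impute_snp_freqs(track, panel)
  expect_equal(imp[, 1], as.numeric(panel$matrix[, 3]))

  # mixed track: hand inner product, and bounds
  f <- c(0.25, 0.75, 0, 0)
  track$freqs <- array(rep(f, each = W), c(W, 4, 1))
  imp2 <- impute_snp_freqs(track, panel)
  expect_equal(imp2[, 1],
               as.numeric(panel$matrix %*% f))
  expect_true(all(imp2 >= 0 & imp2 <= 1))
})

test_that("nearest-window lookup breaks ties toward the lower center", {
  centers <- c(0, 1, 2)
  idx <- poolxqtl:::nearest_window(c(0, 0.49, 0.5, 0.51, 1.5, 2), centers)
  expect_identical(idx, c(1L, 1L, 1L, 2L, 2L, 3L))
})

test_that("noiseless end-to-end recovery through the full window chain", {
  panel <- toy_founders(n_sites = 80, n_founders = 4, seed = 12,
                        total_cM = 10)
  map <- toy_map(10, 81000)
  windows <- define_windows(map, panel, 1.5, 0.25)
  f_true <- c(0.4, 0.3, 0.2, 0.1)
  y <- as.numeric(panel$matrix %*% f_true)
  big <- 1e6  # effectively infinite coverage: y is exact
  pool <- pool_counts("s1", "control", 1, 100, ref = (1 - y) * big,
                      alt = y * big)
  track <- fit_haplotype_track(list(pool), panel, windows)
  ident <- !grepl("non_identifiable|few_sites", track$flag[, 1])
  expect_gt(sum(ident), 0)
  err <- apply(track$freqs[ident, , 1, drop = FALSE], 1,
               function(z) max(abs(z - f_true)))
  expect_lt(max(err), 1e-6)
  imp <- impute_snp_freqs(track, panel)
  expect_lt(max(abs(imp[, 1] - y)), 1e-6)
})

test_that("pseudo-counts scale frequencies by 2Nk", {
  pc <- to_pseudo_counts(0.5, 100, 1)
  expect_equal(pc, list(ref = 100, alt = 100))
  expect_equal(to_pseudo_counts(0, 50, 1)$alt, 0)
  pc7 <- to_pseudo_counts(c(0.2, 0.9), 100, 0.7)
  expect_equal(pc7$ref + pc7$alt, rep(2 * 100 * 0.7, 2))
  expect_equal(pc7$alt, c(0.2, 0.9) * 140)
  expect_error(to_pseudo_counts(0.5, 10, 0), "k >")
})

test_that("the efficiency factor k rescales CMH statistics without reordering", {
  # 2x2xK tables built from the same frequencies at k = 1 vs k = 0.7
  freqs_case <- c(0.55, 0.52)
  freqs_ctrl <- c(0.45, 0.50)
  mk_tab <- function(k) {
    tabs <- array(0, c(2, 2, 2))
    for (r in 1:2) {
      ctl <- to_pseudo_counts(freqs_ctrl[r], 200, k)
      cas <- to_pseudo_counts(freqs_case[r], 150, k)
      tabs[, , r] <- rbind(c(ctl$ref, ctl$alt), c(cas$ref, cas$alt))
    }
    tabs
  }
  s1 <- cmh_2x2xK(mk_tab(1), variance = "uncorrected")$statistic
  s7 <- cmh_2x2xK(mk_tab(0.7), variance = "uncorrected")$statistic
  expect_equal(s7 / s1, 0.7, tolerance = 1e-12)
  # classical variant: within 1% at these totals
  c1 <- cmh_2x2xK(mk_tab(1))$statistic
  c7 <- cmh_2x2xK(mk_tab(0.7))$statistic
  expect_equal(c7 / c1, 0.7, tolerance = 0.01)
})
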