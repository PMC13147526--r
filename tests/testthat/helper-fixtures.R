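# Shared fixtures and independent oracles.  Expensive simulated panels are
# built once per suite run and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# calibration panel: reduced Ne with a long region keeps the runtime down
# while leaving > 5,000 intermediate-frequency sites; the calibration
# properties tested on it do not depend on the absolute theta
ks_panel <- function() {
  cached("ks_panel",
         simulate_neutral_haplotypes(100, 1.6e6, N_e = 2e5, u = 5e-9,
                                     r = 2e-8, seed = 101))
}

# keep at most one site per `by`-site stride (cheap LD thinning)
stride_thin <- function(idx, by) idx[seq(1, length(idx), by = by)]

# full-size sample (n = 500) panel, region scaled down; used by the
# power-sweep acceptance runs
fig1_panel <- function() {
  cached("fig1_panel",
         simulate_neutral_haplotypes(500, 1e5, N_e = 1e6, u = 5e-9,
                                     r = 2e-8, seed = 202))
}

# small hand-built haplotype panel with known frequencies
hand_panel <- function() {
  H <- rbind(c(1, 1, 0, 1, 0),
             c(1, 0, 0, 1, 0),
             c(0, 1, 1, 1, 0),
             c(0, 0, 0, 1, 1))
  # freqs: 0.5, 0.5, 0.25, 1 -> monomorphic not allowed; use 0.75, 0.25
  H[4, 4] <- 0L
  haplotype_panel(H, c(10L, 20L, 30L, 40L, 50L), 100)
}

# toy founder panel on a uniform 0-10 cM map
toy_founders <- function(n_sites = 40, n_founders = 4, seed = 5,
                         total_cM = 10) {
  withr_seed <- function(expr) poolxqtl:::with_seed(seed, expr)
  M <- withr_seed({
    m <- matrix(rbinom(n_sites * n_founders, 1, 0.5), n_sites)
    repeat {
      ac <- rowSums(m)
      bad <- which(ac == 0 | ac == n_founders)
      if (length(bad) == 0) break
      m[bad, ] <- rbinom(length(bad) * n_founders, 1, 0.5)
    }
    m
  })
  pos <- seq(1000L, by = 1000L, length.out = n_sites)
  founder_panel(sprintf("F%d", seq_len(n_founders)), "chr1", pos, M,
                seq(0, total_cM, length.out = n_sites),
                ref = rep("A", n_sites), alt = rep("T", n_sites))
}

toy_map <- function(total_cM = 10, L = 41000) {
  genetic_map("chr1", c(1, L), c(0, total_cM))
}

# random points on the simplex (independent oracle for the LSEI fits)
rdirichlet1 <- function(n, k) {
  m <- matrix(rgamma(n * k, 1), nrow = k)
  t(m) / colSums(m)
}

# dense grid on the 2-simplex
simplex_grid_2 <- function(res = 1e-3) {
  t0 <- seq(0, 1, by = res)
  cbind(t0, 1 - t0)
}

lsei_objective <- function(H, y, f) sum((as.vector(H %*% f) - y)^2)

# independent CMH oracle (integer tables, K >= 2 strata)
cmh_oracle <- function(tabs) {
  unname(mantelhaen.test(as.table(tabs), correct = FALSE)$statistic)
}

# small complete xqtl dataset shared by scan tests
tiny_xqtl <- function() {
  cached("tiny_xqtl", {
    panel <- toy_founders(n_sites = 120, n_founders = 4, seed = 9,
                          total_cM = 20)
    map <- toy_map(20, 121000)
    qtl <- qtl_spec("chr1", 60000, c(1, 0, 0, 0), env_sd = 1)
    design <- experiment_design(K = 4, n_ctrl = 120, n_case = 80, q = 0.1,
                                coverage_ctrl_total = 400,
                                coverage_case_total = 320,
                                two_control_pool_reps = 2)
    ds <- generate_xqtl_dataset(design, panel, qtl, map, G = 20, seed = 42)
    list(panel = panel, map = map, qtl = qtl, design = design, dataset = ds)
  })
}
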