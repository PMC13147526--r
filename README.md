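# poolxqtl

Power analysis and founder-imputation genome scans for pool-seq X-QTL
mapping.

## The problem this package addresses

Pool-seq case-control studies estimate allele frequencies from read
counts, so a frequency estimate's standard error is governed by the
sequencing coverage *C* — `sqrt(pq/C)` — not by the (usually much larger)
number of pooled chromosomes *2N*. At realistic coverages this noise
swamps allele-frequency differences of a few percent, and the resulting
flat Manhattan plot is easily misread as evidence that a trait is highly
polygenic when a major-effect locus is in fact segregating.

In a multiparent population (MPP) with a known set of founder haplotypes
there is a way out: founder haplotype frequencies can be estimated from
pooled SNP frequencies by constrained least squares in sliding
genetic-map windows,

```
f_hat = argmin || H f - y ||_2   subject to  f >= 0,  sum_j f_j = 1,
```

where `H` is the window's site-by-founder 0/1 matrix and `y` the observed
pooled frequencies. Window aggregation makes `f_hat` (and SNP frequencies
imputed back as `sum_j f_hat_j h_ij`) accurate on the *2N* scale rather
than the *C* scale. Converted to pseudo-counts (`freq x 2Nk`) and tested
with Cochran–Mantel–Haenszel statistics stratified over experimental
replicates, these imputation-based scans recover localized association
peaks that the direct read-count scan cannot resolve.

The package is aimed at people designing or interpreting pool-seq and
X-QTL (bulked segregant) experiments. It provides, as tested R code:

* a neutral coalescent haplotype simulator (msprime backend) —
  `simulate_neutral_haplotypes()`;
* an in-silico pool-seq case-control experiment with negative-binomial
  overdispersed coverage (variance = 2 x mean) and per-SNP chi-square
  scans — `run_power_sweep()`, `run_fig1()`;
* a synthetic known-founder advanced-intercross (X-QTL) generator: mosaic
  genomes, a planted liability QTL, ~7% truncation-selected case pools,
  12 replicates, exact truth tables — `generate_xqtl_dataset()`;
* constrained least-squares founder-frequency inference, SNP imputation
  and pseudo-counts — `estimate_founder_freqs()`, `impute_snp_freqs()`,
  `to_pseudo_counts()`;
* the three CMH genome scans and their comparison —
  `scan_direct_snp()`, `scan_haplotype()`, `scan_imputed_snp()`,
  `compare_scans()`, orchestrated by `run_xqtl_compare()`.

## Worked example

The headline experiment: a 12-replicate synthetic X-QTL dataset
(~4,800 control / ~3,420 case individuals, aggregate coverages 983x/739x,
~20,000 SNPs on a 50-cM chromosome, one planted QTL at 25 cM whose
favored founder shifts case frequencies by ~8 points), scanned three
ways.

```r
library(poolxqtl)
res <- run_xqtl_compare(xqtl_config(), seed = 1)
print(res$comparison, digits = 4)
print(res$rmse$rmse, digits = 3)
```

```
         scan global_max argmax_cM qtl_peak background_max    gap n_hits
1  direct_snp      10.36     25.39    10.36          7.828  2.535     62
2   haplotype      55.06     24.75    55.06         25.472 29.592     34
3 imputed_snp      60.82     24.63    60.82         35.256 25.566    839
  cluster_score cluster_fraction qtl_localized
1            37          0.04945          TRUE
2             8          1.00000          TRUE
3           288          0.36887          TRUE

  treatment rmse_direct rmse_imputed
1   control      0.0132      0.00204
2      case      0.0152      0.00239
```

Reading the numbers: imputed SNP frequencies are ~6x more accurate than
directly ascertained ones (RMSE 0.002 vs 0.013–0.015) — that is the whole
mechanism. On the -log10(p) scale the direct scan's peak stands only
2.5 units above its genome-wide background, while the imputation-based
scans tower 25–30 units above theirs and localize the QTL to within half
a centiMorgan (argmax 24.6–24.8 vs truth 25.0). The imputation-based
statistics are deliberately on an inflated scale (pseudo-counts at
efficiency `k = 1` overstate the effective sample size by roughly 30%);
the inflation is a genome-wide constant, so peak ranking and localization
are unaffected — see the methods vignette.

The power side of the argument (why the direct scan is blurred) comes
from the pool-seq case-control sweep:

```r
panel <- subsample_panel(simulate_neutral_haplotypes(500, 1e5, seed = 202),
                         maf_min = 0.05)
run_power_sweep(panel, coverages = c(400, 1000, 5000),
                delta_ps = c(0.04, 0.08), n_reps = 50, seed = 11)
```

```
  coverage delta_p n_reps power false_signal_rate mean_focal_neg_log10_p
1      400    0.04     50  0.02              0.06              0.8564001
2     1000    0.04     50  0.00              0.12              1.5759426
3     5000    0.04     50  0.38              0.66              4.8575417
4      400    0.08     50  0.00              0.12              1.9767417
5     1000    0.08     50  0.24              0.40              3.9742174
6     5000    0.08     50  1.00              1.00             16.0453044
```

An 8% frequency difference — large by GWAS standards, and the same size
as the planted QTL's shift above — is reliably detected only at 5,000x
coverage; the ~861x of the X-QTL design has essentially no per-SNP power,
which is exactly why the direct scan needs rescuing by imputation.

Command-line equivalents (`inst/exec/poolxqtl`):

```sh
poolxqtl run-xqtl-compare --seed 1 --out out/xqtl
poolxqtl run-fig1 --coverage 400,1000,5000 --delta 0.04,0.08 \
         --replicates 50 --seed 11 --out out/fig1
poolxqtl simulate-mpp --seed 1 --out out/mpp     # dataset TSV/SYNC only
```

## Layout

```
R/                  implementation (simulators, inference, CMH scans, CLI)
inst/python/        msprime backend helper
inst/exec/poolxqtl  command-line front end
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, assumptions, design choices)
```
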