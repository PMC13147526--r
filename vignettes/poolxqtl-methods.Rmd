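---
title: "Pool-seq power, founder imputation, and the three genome scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq power, founder imputation, and the three genome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pool-seq estimates a population allele frequency from the reads covering a
site rather than from genotypes. When the number of pooled chromosomes $2N$
greatly exceeds the sequencing coverage $C$, the estimate is unbiased but
its standard error is governed by the reads: $\sqrt{pq/C}$. In a
case-control genome scan this is the quantity that sets power, and at the
coverages that pool-seq studies typically achieve (hundreds of x) it is too
large to reliably detect allele-frequency differences of a few percent. A
Manhattan plot from such a scan shows no clear peaks even when a
large-effect locus is segregating — a pattern easily misread as a polygenic
architecture, when it is actually statistical noise masking a simple one.

In a multiparent population (MPP) descended from a small set of known,
sequenced founders the limitation can be side-stepped. Local founder
haplotype frequencies can be estimated from the pooled SNP frequencies by
constrained least squares in sliding genetic-map windows; because a window
aggregates hundreds of SNPs, the resulting estimates (and the SNP
frequencies imputed back from them) have errors governed by the number of
pooled individuals, approaching what genotyping every individual would
give, rather than by coverage. The package implements both routes end to
end on synthetic data so the mechanism can be demonstrated and tested:
simulate, scan directly, scan through imputation, compare.

## Models and procedures

### Neutral haplotype panels

`simulate_neutral_haplotypes()` draws $n$ haplotypes from a neutral
coalescent with recombination (msprime backend, infinite-sites binary
mutations). Defaults are wild *Drosophila melanogaster*-like:
$N_e = 10^6$, $u = 5\times 10^{-9}$, $r = 2\times 10^{-8}$ per bp per
generation, with the standard diploid scaling $\theta = 4N_e u$ (the
backend runs on a haploid timescale, so it is handed a haploid population
of $2N_e$ genomes; the test suite pins this against the Watterson
expectation $E[S] = 4 N_e u L \sum_{i<n} 1/i$). "Common SNPs" are
operationalized as panel MAF $\ge$ 0.05 (`subsample_panel()`), a
conventional default; the cutoff only changes how many sites are tested.

### The pool-seq case-control experiment

`run_power_sweep()` rebuilds the simulated experiment: a control pool of
$M = 10{,}000$ haplotype copies drawn with replacement from the panel, and
a case pool built by stratified resampling conditional on one
intermediate-frequency focal SNP (MAF 0.30–0.70) shifting by exactly
$\Delta p$ (the focal ALT count is fixed at
$\mathrm{round}((p \pm \Delta p)M)$; within each focal allele class,
haplotypes are resampled uniformly, so other sites move only through
linkage). Stratified construction was chosen over rejection sampling
because it makes the planted effect exact and the experiment reproducible
draw by draw. The shift direction defaults to increasing the ALT allele;
the construction is symmetric.

Sequencing is simulated per site as total coverage
$\sim \mathrm{NB}(\text{size} = \mu, \ \mu = C)$ — an overdispersed
Poisson with variance $2\mu$ — and ALT reads binomial in the realized
coverage. Each site is tested with a 2x2 Pearson chi-square (no continuity
correction); zero-margin sites are reported with $p = 1$ rather than
dropped so site vectors stay aligned. No sequencing-error or mapping-bias
model is included: the target of study is pure sampling noise.

At the default grid (400/1,000/5,000x, $\Delta p$ = 4%/8%, threshold
$-\log_{10} p \ge 5$) the sweep reproduces the qualitative result that an
8% shift is reliably detected only at 5,000x. Two caveats learned from the
null cells: (i) detection rates below 5,000x sit at the noise floor, so
comparisons between them are only meaningful up to binomial error; and
(ii) at very high coverage the scan starts to resolve the *true* finite-
pool resampling differences ($\mathrm{sd} \approx \sqrt{pq/M}$), which
inflates the genome-wide exceedance rate — visible as a rising
`false_signal_rate` column with coverage even at $\Delta p = 0$.

### The synthetic X-QTL dataset

`generate_xqtl_dataset()` emulates a zinc-resistance-style X-QTL design on
an 8-founder advanced intercross. Its stated world (defaults in
`xqtl_config()` / `experiment_design()`):

* **Founders**: F = 8 haplotypes sampled from a neutral panel (the
  founders of the DSPR are natural chromosomes, so no inbred-line descent
  is simulated); sites segregating among the founders are kept, thinned to
  ~20,000 SNPs on one chromosome with a linear 50-cM map.
* **Mosaics**: after G = 33 generations (midpoint of a 31–36-generation
  maintenance regime) each haploid genome is a founder mosaic generated by
  a one-shot Poisson process: breakpoint count
  $\sim \mathrm{Poisson}(G \times \text{map length in Morgans})$,
  positions uniform in cM, founder labels i.i.d. uniform. This replaces an
  explicit generation-by-generation pedigree — after tens of random-mating
  generations the breakpoint process is approximately Poisson, and founder
  frequency drift is deliberately omitted (it is incidental to the power
  comparison).
* **Phenotype and selection**: a single additive liability QTL at
  mid-chromosome. One founder carries an effect of 0.4 per allele copy
  against environmental noise with sd 1; truncation selection keeps the
  top 7% as cases. By the standard selection-intensity calculation
  ($i \approx 1.91$ at 7%) this shifts the favored founder's frequency
  among cases by about +0.08 — deliberately the same 8% regime the power
  sweep shows is *undetectable* by direct pool-seq below ~5,000x but
  trivially detectable from counts on the $2N \approx 8{,}000$ scale. The
  liability construction stands in for survival at 25 mM zinc chloride; no
  mortality dynamics are modeled.
* **Design**: K = 12 replicates; 400 control and 285 case individuals per
  replicate (totals ~4,800/~3,420, matching the published totals of 4,831
  and 3,448 at a round per-replicate size); aggregate coverages 983x
  (control) and 739x (case) split evenly across replicate pools;
  replicates 5, 6, 8, 11, 12 carry two equally sized control pools.
  Per-replicate pool sizes and coverages are not published numerically, so
  these splits are configuration, not claims.

Truth tables (founder and SNP frequencies of every pool) are exact
bookkeeping over the mosaic segments, so estimator error can be measured
without Monte Carlo noise.

### Founder-frequency inference and imputation

For each sample and each sliding window (full width 1.5 cM, step 0.25 cM),
`estimate_founder_freqs()` solves

$$\hat f = \arg\min_f \| H f - y \|_2 \quad \text{s.t.}\quad f \ge 0,\
\textstyle\sum_j f_j = 1,$$

where $H$ is the window's site-by-founder 0/1 matrix and $y$ the observed
pooled frequencies ALT/(REF+ALT) at sites with coverage $\ge$ 10 (ratio
estimates at tiny coverage destabilize the fit). The solver is a
Lawson–Hanson NNLS warm start (sum-to-one row at large weight) followed by
an exact KKT active-set refinement, so solutions satisfy the constraints
to machine precision; the test suite verifies the argmin against simplex
grid, vertex and 10,000-random-point oracles rather than trusting the
algorithm. Numerical choices: founders with identical in-window states are
collapsed for the fit and their fitted total split equally (flagged
`non_identifiable`); windows with fewer usable sites than founders are
flagged `few_sites`; rank-deficient supports fall back to a ridge-damped
minimum-norm solution. The step of 0.25 cM (window width 1.5) makes the
"nearest window" assignment smooth; both are configurable. Fits are
independent across samples, and sites are not weighted by coverage inside
a window.

`impute_snp_freqs()` then sets each site's imputed frequency to
$\sum_j \hat f_j h_{ij}$ using the window whose center is nearest in cM
(ties to the lower center — a documented arbitrary choice). Because
$\hat f$ is on the simplex and $h \in \{0,1\}$, imputed frequencies are
automatically in $[0,1]$.

### Pseudo-counts and the efficiency factor k

`to_pseudo_counts()` converts frequencies to real-valued counts
$f \cdot 2Nk$, treating an imputed frequency as if it came from genotyping
the $N$ pooled diploids. Imputation is not that efficient — the effective
sample size is smaller by a factor $k < 1$ — and since chi-square
statistics scale linearly with sample size, running the tests at $k = 1$
inflates the imputation-based statistics by a constant genome-wide factor
(about 30% for window haplotype imputation against high-coverage
validation). The default is $k = 1$, reproducing that inflated scale
deliberately: the inflation is uniform along the genome, so peak ranking
and localization are unaffected, and the constant is exposed as a
parameter (`k_efficiency`) rather than hidden. Pseudo-counts are passed to
the tests unrounded; the CMH formulas are evaluated on real tables.

### The three scans and their comparison

All tests are Cochran–Mantel–Haenszel, stratified by the K = 12
replicates; replicates with two control pools have their control counts
summed within replicate to preserve the stratification:

* `scan_direct_snp()` — per site, 2x2xK on observed REF/ALT read counts;
* `scan_haplotype()` — per window, generalized CMH (general association,
  df = F − 1) on founder pseudo-counts, the canonical J-category extension
  (a per-founder 2x2 option would bracket the same information);
* `scan_imputed_snp()` — per site, 2x2xK on imputed REF/ALT pseudo-counts.

Both the classical $T^2(T-1)$ variance and a no-$(T-1)$ variant are
implemented (the latter scales *exactly* linearly under cell
multiplication; the classical factor is $(cT-1)/(T-1)$ per stratum, which
straddles $c$ and converges to it as totals grow). Classical is the
default. Degenerate strata contribute nothing; a singular generalized-CMH
covariance falls back to a pseudo-inverse with the effective df reported;
p-values are floored at $10^{-300}$ so $-\log_{10} p$ stays finite.

`compare_scans()` summarizes each scan by its global peak, the peak within
±1.5 cM of the true QTL, the background maximum outside that window, the
peak−background gap, and two clustering summaries of above-threshold hits:
`cluster_score` (median count of other hits within ±1 cM) and
`cluster_fraction` (median fraction of *loci* within ±1 cM that are hits).
The raw count is not comparable across scans with different locus
spacings — a window-level scan at 0.25-cM step can never score above 8 —
which is why the density-independent fraction is reported alongside it.

## What a green test does and does not establish

The generator reproduces the *sampling structure* of a replicated X-QTL
experiment: known founders, mosaic genomes, truncation-selected cases,
overdispersed pool-seq counts, replicate strata. It deliberately omits
sequencing error, mapping and reference bias, repetitive-region artifacts,
founder-frequency drift, sex chromosomes and viability-selection dynamics.
Consequently the synthetic direct-SNP scan is clean: when it fails to show
the QTL it fails for the honest reason (sampling noise), and it shows none
of the dispersed artifact hits that real high-coverage data can produce.
A green acceptance suite therefore establishes the power mechanism — that
imputation-based frequency estimates are several-fold more accurate and
that this alone converts a blurred scan into a localized one — not that
any particular real dataset is artifact-free.

Because the planted QTL here shifts frequencies by ~8 points (large by
GWAS standards), the direct scan does retain a modest peak at the QTL at
~861x mean coverage; the acceptance criteria are comparative (RMSE
ordering, gap ordering, clustering ordering) rather than claims that the
direct scan sees nothing.

## Numerical and design choices not fixed by the problem

* Seeds: every stage derives its own stream via a stable FNV-style hash
  (`derive_stage_seed()`), making outputs pure functions of
  (config, master seed) and independent of call order.
* Region lengths in tests and acceptance runs are scaled down from 1 Mb
  (the coalescent at $\rho = 4N_e r L \sim 10^5$ costs minutes); per-site
  focal power does not depend on region length, and site counts are
  reported alongside results.
* Config files are JSON with constructor-validated keys; unknown keys are
  a hard error because a silently ignored typo in a power study produces
  confidently wrong numbers.
* Biallelic SNPs only; sites with missing founder states are excluded
  from window fits. Multi-allelic/indel handling is out of scope.
* TSV outputs print numeric values at 10 significant digits so reruns are
  byte-identical.

## Known limitations

* The haplotype scan reports one statistic per window center; sub-window
  localization is not attempted.
* No uncertainty is attached to $\hat f$ beyond the residual norm and
  identifiability flags.
* The generalized CMH uses the large-sample chi-square reference; with
  very few informative strata its calibration is approximate (the
  permutation-null test in the suite checks the regime used here).
* `k_efficiency` rescales statistics globally; it does not model
  locus-specific imputation quality (e.g. windows where founders are
  locally indistinguishable are flagged instead).
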