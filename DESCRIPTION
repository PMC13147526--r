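Package: poolxqtl
Title: Power Analysis and Founder-Imputation Genome Scans for Pool-Seq X-QTL Mapping
Version: 0.1.0
Authors@R:
    person("Pool-seq X-QTL", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the statistical power of pooled-sequencing
    (pool-seq) case-control genome scans and for recovering that power in
    multiparent populations with known founders. Provides a neutral-coalescent
    haplotype simulator (backed by msprime), an in-silico pool-seq case-control
    experiment with overdispersed negative-binomial coverage, a synthetic
    advanced-intercross (X-QTL) data generator with truncation-selected case
    pools, constrained least-squares estimation of founder haplotype
    frequencies in sliding genetic-map windows, imputation of SNP frequencies
    from founder frequencies, and Cochran-Mantel-Haenszel genome scans on
    direct read counts, imputed haplotype pseudo-counts, and imputed SNP
    pseudo-counts, together with scan-comparison summaries and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the msprime package on the PATH as
    'python' (used only by the neutral coalescent simulator).
Config/testthat/edition: 3
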