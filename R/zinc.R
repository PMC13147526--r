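#' Published zinc X-QTL design summary
#'
#' The design-level numbers of the zinc-resistance X-QTL experiment that
#' this package's synthetic generator emulates: 12 replicate selection
#' assays on an 8-founder advanced intercross, case pools drawn from the
#' ~7% most resistant females, 4,831 control and 3,448 case individuals
#' pooled in total, and aggregate sequencing coverages of 983x (control)
#' and 739x (case).  These are experiment inputs (sample sizes and
#' coverages), not analysis results; they parameterize defaults and the
#' sample-size bookkeeping (e.g. mean autosomal allele count per treatment
#' 2 x 4,140 = 8,280, roughly 10x the mean coverage — the core of the
#' power argument).
#'
#' @return named list with `K`, `n_founders`, `selection_fraction`,
#'   `control_individuals`, `case_individuals`, `coverage_control`,
#'   `coverage_case`, `generations` (range of intercross maintenance).
#' @export
zinc_xqtl_summary <- function() {
  list(K = 12L, n_founders = 8L, selection_fraction = 0.07,
       control_individuals = 4831L, case_individuals = 3448L,
       coverage_control = 983, coverage_case = 739,
       generations = c(31L, 36L))
}
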