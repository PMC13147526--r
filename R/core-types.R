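## Core data containers shared by every stage: founder panels, pooled read
## counts, genetic maps and scan results.  All coordinates are 1-based bp
## (VCF convention); genetic positions are centiMorgans.

#' Founder haplotype panel
#'
#' A site-by-founder matrix of biallelic allele codes (0 = REF, 1 = ALT,
#' `NA` = missing) together with physical and genetic coordinates.  This is
#' the "known founder states" object that haplotype inference and SNP
#' imputation condition on; for a DSPR-like design there are F = 8 founders.
#'
#' @param founder_ids character vector of founder labels (length F).
#' @param chrom chromosome label per site (length S).
#' @param pos 1-based integer bp positions, strictly increasing within a
#'   chromosome.
#' @param matrix S x F matrix with entries 0, 1 or `NA`.
#' @param map_cM numeric genetic position per site (cM), non-decreasing with
#'   `pos` within a chromosome.
#' @param ref,alt optional REF/ALT nucleotide labels per site (needed only
#'   for SYNC export).
#' @return An object of class `founder_panel`.
#' @export
founder_panel <- function(founder_ids, chrom, pos, matrix, map_cM,
                          ref = NULL, alt = NULL) {
  founder_ids <- as.character(founder_ids)
  pos <- as.integer(pos)
  chrom <- as.character(chrom)
  mat <- base::as.matrix(matrix)
  storage.mode(mat) <- "integer"
  S <- length(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, S)
  stopifnot(nrow(mat) == S, length(chrom) == S, length(map_cM) == S)
  if (ncol(mat) != length(founder_ids)) {
    stop("matrix must have one column per founder")
  }
  bad <- !(mat %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("founder matrix entries must be 0, 1 or NA")
  for (ch in unique(chrom)) {
    i <- chrom == ch
    if (is.unsorted(pos[i], strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
    if (is.unsorted(map_cM[i])) {
      stop("map_cM must be non-decreasing within chromosome ", ch)
    }
  }
  colnames(mat) <- founder_ids
  structure(
    list(founder_ids = founder_ids, chrom = chrom, pos = pos,
         matrix = mat, map_cM = as.numeric(map_cM),
         ref = ref, alt = alt),
    class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("<founder_panel> %d sites x %d founders, %d chromosome(s)\n",
              length(x$pos), length(x$founder_ids),
              length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.founder_panel <- function(x) c(length(x$pos), length(x$founder_ids))

#' Pooled read counts for one sample
#'
#' REF/ALT read counts at every panel site for one pooled DNA sample, with
#' the design metadata needed by the scans: treatment arm, replicate index,
#' and the number of diploid individuals N contributing to the pool (the
#' quantity whose doubling, 2N, sets the pseudo-count scale).
#'
#' @param sample_id character scalar.
#' @param treatment `"case"` or `"control"`.
#' @param replicate positive integer replicate index.
#' @param n_individuals diploid pool size N (> 0).
#' @param ref,alt non-negative integer (or real, for pseudo-counts) vectors
#'   aligned to the site index of the companion panel/sites table.
#' @return An object of class `pool_counts`.
#' @export
pool_counts <- function(sample_id, treatment, replicate, n_individuals,
                        ref, alt) {
  treatment <- match.arg(treatment, c("case", "control"))
  replicate <- as.integer(replicate)
  stopifnot(length(ref) == length(alt), n_individuals > 0, replicate >= 1L)
  if (any(ref < 0) || any(alt < 0)) stop("counts must be non-negative")
  if (anyNA(ref) || anyNA(alt)) stop("counts must not be missing")
  structure(
    list(sample_id = as.character(sample_id), treatment = treatment,
         replicate = replicate, n_individuals = as.numeric(n_individuals),
         ref = as.numeric(ref), alt = as.numeric(alt)),
    class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("<pool_counts> %s (%s, rep %d, N = %g): %d sites, mean coverage %.1f\n",
              x$sample_id, x$treatment, x$replicate, x$n_individuals,
              length(x$ref), mean(x$ref + x$alt)))
  invisible(x)
}

#' Genetic map
#'
#' Ordered (bp, cM) anchor pairs per chromosome supporting piecewise-linear
#' interpolation between physical and genetic coordinates.
#'
#' @param chrom,pos,cM equal-length vectors of anchors; within each
#'   chromosome `pos` must be strictly increasing and `cM` non-decreasing,
#'   with at least two anchors.
#' @return An object of class `genetic_map` (a data.frame).
#' @export
genetic_map <- function(chrom, pos, cM) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   cM = as.numeric(cM), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    if (sum(i) < 2L) stop("need at least 2 anchors on chromosome ", ch)
    if (is.unsorted(df$pos[i], strictly = TRUE)) {
      stop("anchor bp must be strictly increasing on chromosome ", ch)
    }
    if (is.unsorted(df$cM[i])) {
      stop("anchor cM must be non-decreasing on chromosome ", ch)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Interpolate genetic-map position
#'
#' Piecewise-linear interpolation of cM at physical positions, exact at
#' anchors.  Extrapolation is refused: positions outside the anchored range
#' of their chromosome are an error.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label (scalar, or vector recycled against `bp`).
#' @param bp physical position(s), 1-based.
#' @return numeric vector of cM positions.
#' @export
interpolate_cM <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"))
  n <- max(length(chrom), length(bp))
  chrom <- rep_len(as.character(chrom), n)
  bp <- rep_len(as.numeric(bp), n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    a <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0L) stop("chromosome ", ch, " not in map")
    x <- bp[i]
    if (any(x < a$pos[1L] | x > a$pos[nrow(a)])) {
      stop("position outside anchored range on chromosome ", ch,
           " (no extrapolation)")
    }
    out[i] <- approx(a$pos, a$cM, xout = x, ties = "ordered")$y
  }
  out
}

#' Total genetic length of a map, in Morgans
#'
#' @param map a [genetic_map()].
#' @return named numeric vector, one Morgan length per chromosome.
#' @export
map_length_morgans <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  vapply(split(map$cM, map$chrom), function(z) (max(z) - min(z)) / 100,
         numeric(1))
}

#' Assemble a scan-result table
#'
#' Normalizes per-locus test results into the common Manhattan-ready layout
#' used by all three scans.  p-values are floored at 1e-300 so that
#' -log10(p) stays finite.
#'
#' @param locus_id locus identifier (site index or window center label).
#' @param chrom,pos_bp,cM locus coordinates (`pos_bp` may be NA for window
#'   results).
#' @param statistic non-negative test statistics.
#' @param df degrees of freedom per locus.
#' @param p_value p-values in (0, 1].
#' @param scan_type one of `"direct_snp"`, `"haplotype"`, `"imputed_snp"`.
#' @param flag optional character diagnostic flags ("" if clean).
#' @return data.frame of class `scan_result`.
#' @export
scan_result <- function(locus_id, chrom, pos_bp, cM, statistic, df, p_value,
                        scan_type, flag = "") {
  scan_type <- match.arg(scan_type, c("direct_snp", "haplotype", "imputed_snp"))
  p_value <- pmax(pmin(p_value, 1), 1e-300)
  stopifnot(all(statistic >= 0 | is.na(statistic)))
  out <- data.frame(
    locus_id = locus_id, chrom = as.character(chrom),
    pos_bp = as.numeric(pos_bp), cM = as.numeric(cM),
    statistic = as.numeric(statistic), df = as.integer(df),
    p_value = p_value, neg_log10_p = -log10(p_value),
    scan_type = scan_type,
    flag = rep_len(as.character(flag), length(p_value)),
    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}
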