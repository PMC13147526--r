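## Plain-text readers/writers: counts TSV (+ sample metadata sidecar),
## popoolation2-style SYNC, founder-panel TSV and genetic-map TSV.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a pooled counts table
#'
#' The counts TSV has columns `chrom`, `pos`, `ref`, `alt` and one
#' `<sample>_ref`/`<sample>_alt` pair per sample; the sidecar metadata TSV
#' (columns `sample_id`, `treatment`, `replicate`, `n_individuals`) supplies
#' the design labels.  Site order follows file order.
#'
#' @param path counts TSV path.
#' @param meta_path metadata TSV path (default `<path>.meta`).
#' @return list with `sites` (data.frame chrom/pos/ref/alt) and `pools`
#'   (list of [pool_counts()]), class `pool_counts_set`.
#' @export
read_counts_table <- function(path, meta_path = paste0(path, ".meta")) {
  df <- read_tsv_strict(path)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("counts table must have columns chrom, pos, ref, alt")
  }
  if (nrow(df) == 0L) stop("no sites in counts table ", path)
  meta <- read_tsv_strict(meta_path)
  mneed <- c("sample_id", "treatment", "replicate", "n_individuals")
  if (!all(mneed %in% names(meta))) {
    stop("metadata must have columns ", paste(mneed, collapse = ", "))
  }
  pools <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    rc <- df[[paste0(sid, "_ref")]]
    ac <- df[[paste0(sid, "_alt")]]
    if (is.null(rc) || is.null(ac)) {
      stop("counts table lacks columns for sample ", sid)
    }
    if (anyNA(rc) || anyNA(ac)) {
      stop("missing count cell for sample ", sid, " at line ",
           which(is.na(rc) | is.na(ac))[1L] + 1L)
    }
    if (any(rc < 0) || any(ac < 0)) {
      stop("negative count for sample ", sid, " at line ",
           which(rc < 0 | ac < 0)[1L] + 1L)
    }
    pools[[i]] <- pool_counts(sid, meta$treatment[i], meta$replicate[i],
                              meta$n_individuals[i], rc, ac)
  }
  structure(list(sites = df[need], pools = pools), class = "pool_counts_set")
}

#' Write a pooled counts table (+ metadata sidecar)
#'
#' Inverse of [read_counts_table()]; write-then-read round-trips counts
#' exactly.
#'
#' @param pools list of [pool_counts()].
#' @param sites data.frame with chrom, pos, ref, alt.
#' @param path output TSV path.
#' @param meta_path metadata output path (default `<path>.meta`).
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(pools, sites, path,
                               meta_path = paste0(path, ".meta")) {
  df <- sites[c("chrom", "pos", "ref", "alt")]
  for (p in pools) {
    stopifnot(inherits(p, "pool_counts"), length(p$ref) == nrow(df))
    df[[paste0(p$sample_id, "_ref")]] <- fmt_num(p$ref)
    df[[paste0(p$sample_id, "_alt")]] <- fmt_num(p$alt)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    sample_id = vapply(pools, `[[`, character(1), "sample_id"),
    treatment = vapply(pools, `[[`, character(1), "treatment"),
    replicate = vapply(pools, `[[`, integer(1), "replicate"),
    n_individuals = vapply(pools, `[[`, numeric(1), "n_individuals"))
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## print numbers exactly for integers, 10 significant digits otherwise,
## so rewritten TSVs are byte-stable across runs
fmt_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         sprintf("%.10g", x))
}

#' Write pooled counts in SYNC format
#'
#' popoolation2-style SYNC: `chrom  pos  ref-base` then one
#' `A:T:C:G:N:del` colon-separated count field per pool, tab-separated, in
#' the order of `pools`.  REF counts land in the REF-base slot and ALT
#' counts in the ALT-base slot; all other slots are zero.
#'
#' @param pools list of [pool_counts()].
#' @param sites data.frame with chrom, pos and nucleotide `ref`/`alt`
#'   columns (A/C/G/T).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(pools, sites, path) {
  if (inherits(sites, "founder_panel")) {
    sites <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        ref = sites$ref, alt = sites$alt)
  }
  if (is.null(sites$ref) || is.null(sites$alt) ||
      !all(sites$ref %in% c("A", "C", "G", "T")) ||
      !all(sites$alt %in% c("A", "C", "G", "T"))) {
    stop("SYNC export needs A/C/G/T ref and alt labels at every site")
  }
  S <- nrow(sites)
  bases <- c("A", "T", "C", "G")
  ri <- match(sites$ref, bases)
  ai <- match(sites$alt, bases)
  fields <- matrix("", nrow = S, ncol = length(pools))
  for (j in seq_along(pools)) {
    p <- pools[[j]]
    stopifnot(length(p$ref) == S)
    cnt <- matrix(0, nrow = S, ncol = 6)  # A T C G N del
    cnt[cbind(seq_len(S), ri)] <- p$ref
    cnt[cbind(seq_len(S), ai)] <- p$alt
    fields[, j] <- paste(fmt_num(cnt[, 1]), fmt_num(cnt[, 2]),
                         fmt_num(cnt[, 3]), fmt_num(cnt[, 4]),
                         fmt_num(cnt[, 5]), fmt_num(cnt[, 6]), sep = ":")
  }
  lines <- paste(sites$chrom, sites$pos, sites$ref,
                 apply(fields, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a SYNC file back into REF/ALT counts
#'
#' Requires the ALT base per site (SYNC stores only the REF base), e.g. from
#' the founder panel used to write it.
#'
#' @param path SYNC path.
#' @param alt ALT nucleotide per site (A/C/G/T).
#' @return list with `sites` (chrom, pos, ref, alt) and `counts` — a list of
#'   per-pool list(ref, alt) count vectors.
#' @export
read_sync <- function(path, alt) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("no sites in SYNC file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  npool <- length(parts[[1L]]) - 3L
  chrom <- vapply(parts, `[[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[[`, character(1), 2L))
  ref <- vapply(parts, `[[`, character(1), 3L)
  alt <- rep_len(as.character(alt), length(lines))
  bases <- c("A", "T", "C", "G")
  ri <- match(ref, bases)
  ai <- match(alt, bases)
  counts <- vector("list", npool)
  for (j in seq_len(npool)) {
    f <- strsplit(vapply(parts, `[[`, character(1), 3L + j), ":", fixed = TRUE)
    m <- matrix(as.numeric(unlist(f)), ncol = 6, byrow = TRUE)
    counts[[j]] <- list(ref = m[cbind(seq_along(lines), ri)],
                        alt = m[cbind(seq_along(lines), ai)])
  }
  list(sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE),
       counts = counts)
}

#' Read/write a founder panel TSV
#'
#' Layout: columns `chrom`, `pos`, `ref`, `alt`, `cM`, then one 0/1/NA
#' column per founder.
#'
#' @param path TSV path.
#' @return a [founder_panel()].
#' @export
read_founder_panel <- function(path) {
  df <- read_tsv_strict(path)
  fixed <- c("chrom", "pos", "ref", "alt", "cM")
  if (!all(fixed %in% names(df))) {
    stop("founder panel TSV must have columns ", paste(fixed, collapse = ", "))
  }
  fcols <- setdiff(names(df), fixed)
  if (length(fcols) == 0L) stop("founder panel has no founder columns")
  founder_panel(fcols, df$chrom, df$pos,
                as.matrix(df[fcols]), df$cM, ref = df$ref, alt = df$alt)
}

#' @rdname read_founder_panel
#' @param panel a [founder_panel()] to write.
#' @export
write_founder_panel <- function(panel, path) {
  stopifnot(inherits(panel, "founder_panel"))
  df <- data.frame(chrom = panel$chrom, pos = panel$pos,
                   ref = panel$ref %||% rep("A", length(panel$pos)),
                   alt = panel$alt %||% rep("T", length(panel$pos)),
                   cM = sprintf("%.10g", panel$map_cM),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(panel$matrix))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a genetic map TSV (columns chrom, pos, cM)
#'
#' @param path TSV path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("chrom", "pos", "cM") %in% names(df))) {
    stop("genetic map TSV must have columns chrom, pos, cM")
  }
  genetic_map(df$chrom, df$pos, df$cM)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()] to write.
#' @export
write_genetic_map <- function(map, path) {
  df <- data.frame(chrom = map$chrom, pos = fmt_num(map$pos),
                   cM = sprintf("%.10g", map$cM))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
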