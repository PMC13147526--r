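#' Derive a reproducible sub-stream seed
#'
#' Stable, platform-independent hash of `(master_seed, stage_label,
#' replicate_index)` onto `[1, 2^31 - 2]`, used to give every pipeline
#' stage and replicate its own independent, order-independent random
#' stream.  Pure function: identical inputs always give identical seeds,
#' distinct labels give distinct seeds (up to hash collisions).
#'
#' @param master_seed integer master seed.
#' @param stage_label character stage name.
#' @param replicate_index integer replicate number (default 0).
#' @return a single integer seed.
#' @export
derive_stage_seed <- function(master_seed, stage_label, replicate_index = 0L) {
  key <- sprintf("%d|%s|%d", as.integer(master_seed),
                 as.character(stage_label), as.integer(replicate_index))
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    # FNV-1a style fold kept inside double precision (< 2^53)
    h <- ((h %% 8388593) * 16777619 + b) %% 2147483629
  }
  as.integer(h %% 2147483645) + 1L
}
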