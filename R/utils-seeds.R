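#' Derive a stage-specific seed from a root seed
#'
#' All stochastic stages draw their seed deterministically from a single root
#' seed and a stage label, so any stage can be rerun in isolation and still
#' reproduce its output bit-for-bit. The derivation is a small multiplicative
#' hash of the label mixed with the root seed, folded into the signed 32-bit
#' range accepted by [set.seed()].
#'
#' @param seed Integer root seed.
#' @param stage Character stage label (e.g. `"genotypes"`, `"rep3/gwas"`).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, "genotypes")
#' derive_seed(1, "genotypes") == derive_seed(1L, "genotypes")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(stage)) {
    h <- (h * 31 + k) %% 2147483647
  }
  # decorrelate labels sharing a prefix
  h <- (h * 2654435761) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Thin wrapper around [withr::with_seed()]; the caller's RNG state is left
#' untouched.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Cheap content checksum for run manifests
#'
#' FNV-style fold over the serialized object. Not cryptographic; only used to
#' detect that a rerun reproduced a stage output.
#'
#' @param x Any serialisable R object.
#' @return Hex string.
#' @keywords internal
stage_checksum <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  # skip the serialization header (R version stamps differ between sessions)
  raw <- raw[-seq_len(14L)]
  h <- 2166136261
  step <- max(1L, length(raw) %/% 8192L)
  idx <- seq(1L, length(raw), by = step)
  v <- as.integer(raw[idx])
  for (b in v) h <- ((h * 16777619) + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
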