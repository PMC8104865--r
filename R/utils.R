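# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a top-level seed
#'
#' A single top-level seed spawns per-stage seeds deterministically, so a
#' whole synthetic run is a pure function of one integer.
#'
#' @param seed Integer top-level seed.
#' @param stage Character tag of the consuming stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# FNV-1a hash of a character scalar, as 8 hex digits; used for config
# provenance stamps in run reports.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    # xor on the low byte (codes < 256), keeping h a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(code %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, in doubles
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(as.integer(h %/% 65536)), width = 4),
         format(as.hexmode(as.integer(h %% 65536)), width = 4))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Euclidean distance matrix between two point sets (n x 2, m x 2).
cross_dist <- function(a, b) {
  a <- matrix(as.double(a), ncol = 2L)
  b <- matrix(as.double(b), ncol = 2L)
  dx <- outer(a[, 1L], b[, 1L], "-")
  dy <- outer(a[, 2L], b[, 2L], "-")
  sqrt(dx * dx + dy * dy)
}
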