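# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Table-style rounding (0.0005 -> 0.001), unlike [base::round()]'s
#' round-half-even. Used wherever results are reported at the published
#' 3-decimal precision.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so that a single integer seed fully determines output.
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed, staying inside the
# 32-bit signed integer range.
derive_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max, n))
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# FNV-1a 32-bit hash of a character scalar; used to stamp pipeline outputs
# with a configuration fingerprint without external dependencies.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261 # kept as a double in [0, 2^32)
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), b)
    # 32-bit modular multiply split into 16-bit halves to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  # h exceeds the signed-integer range, so format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
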