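# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == trunc(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

# Quantise an array in [0,1] to the 8-bit grid used by PNG files, so that
# in-memory tiles and their on-disk round trip are bit-identical.
quantise8 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  round(x * 255) / 255
}

# Stable non-cryptographic fingerprint of an R object (vectorised weighted
# checksum over its serialisation), used to tie checkpoints, caches and
# selections together.  Collision resistance only needs to catch accidental
# mismatches (stale caches, swapped configs), not adversaries.
fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # drop the serialisation header (carries the R version), keep the payload
  bytes <- bytes[-seq_len(14)]
  w1 <- rep_len(c(1L, 3L, 7L, 11L, 13L, 17L, 19L, 23L), length(bytes))
  w2 <- rep_len(c(29L, 31L, 37L, 41L, 43L, 47L, 53L, 59L, 61L), length(bytes))
  h1 <- sum(as.double(bytes) * w1) %% 2^31
  h2 <- sum(as.double(bytes) * w2) %% 2^31
  sprintf("%08x%08x-%d", h1, h2, length(bytes))
}

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}
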