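# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` runs code untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-item seed from a parent seed; a Lehmer-style mix kept
# strictly below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, index) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483647)
}

# Snap an image to the 256 representable 8-bit levels on [0, 1]; rendering
# and IO both pass through this so in-memory and on-disk pixels agree.
quantize8 <- function(x) {
  .quantize8_cpp(x)
}

is_rgb_image <- function(x) {
  is.numeric(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
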