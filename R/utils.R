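#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and an index, staying within
# 32-bit integer range (R integers are 32-bit).
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + 101 * as.numeric(i)) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

# djb2 string hash, hex-encoded; used only to fingerprint configs in
# provenance logs (not cryptographic).
djb2_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

rms <- function(x) sqrt(mean(x^2))
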