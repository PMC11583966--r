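# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

#' @noRd
is_binary <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}

# Evaluate code with a locally seeded RNG stream; the caller's RNG state is
# untouched.  This is what makes every randomised operation in the package a
# pure function of (inputs, seed).
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Deterministic derived streams; kept strictly below 2^31 so they remain
# valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + offset) %% 2147483629)
}

# Small dependency-free FNV-1a content hash (64-bit arithmetic done in two
# 32-bit halves via doubles), used for provenance logging only.
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - 2^31 * (h %% 2147483648 >= 2^31)), b)
    h <- (as.numeric(h) %% 4294967296 + 4294967296) %% 4294967296
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "abxdelegate_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
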