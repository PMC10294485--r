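# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic 31-bit hash of a string, used to derive per-slide and
# per-epoch seeds from a master seed. Simple multiplicative string hash;
# stability across platforms matters more than dispersion quality.
hash31 <- function(x) {
  stopifnot(length(x) == 1L)
  bytes <- utf8ToInt(as.character(x))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Combine a master seed with string/int components into a 31-bit seed.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    hp <- if (is.character(p)) hash31(p) else as.numeric(p) %% 2147483647
    h <- (h * 48271 + hp + 1) %% 2147483647
  }
  as.integer(h)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Row-softmax of a matrix (or softmax of a vector).
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

# Luma grayscale of an H x W x 3 image array (0-255 scale in, same scale out).
to_gray <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_wsimil <- function(msg, class) {
  stop(structure(
    class = c(class, "wsimil_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
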