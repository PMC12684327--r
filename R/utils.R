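# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Gaussian blur of a matrix by separable convolution; kernel truncated at 3 sigma.
# Edges are renormalised (kernel mass restricted to the grid).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  conv1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- k[j - i + r + 1L]
      out[i] <- sum(w * x[j]) / sum(w)
    }
    out
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}

# Deterministic short fingerprint of an R object (used for provenance checks).
obj_fingerprint <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "")
  # 31-ary polynomial hash modulo a Mersenne prime
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

log_event <- function(log, stage, ...) {
  rec <- list(stage = stage, ...)
  c(log, list(rec))
}
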