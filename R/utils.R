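# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic derived seed for a sub-stream (slice z of a volume, volume i
# of a batch, ...). Kept strictly below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587
  as.integer(s) + 1L
}

# Roll the rows/columns of a matrix so the zero-frequency sample moves between
# corner (FFT native) and center (display) layouts.
fftshift2 <- function(m) {
  d <- dim(m)
  h1 <- (d[1L] + 1L) %/% 2
  h2 <- (d[2L] + 1L) %/% 2
  i <- c(seq_len(d[1L] - h1) + h1, seq_len(h1))
  j <- c(seq_len(d[2L] - h2) + h2, seq_len(h2))
  m[i, j, drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  h1 <- d[1L] %/% 2
  h2 <- d[2L] %/% 2
  i <- c(seq_len(d[1L] - h1) + h1, seq_len(h1))
  j <- c(seq_len(d[2L] - h2) + h2, seq_len(h2))
  m[i, j, drop = FALSE]
}

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
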