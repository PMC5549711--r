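# Literal, loop-based transcriptions of the descriptor definitions, kept
# deliberately naive and independent of the package's vectorized
# implementations.

oracle_composition <- function(g) {
  out <- numeric(3)
  for (k in 1:3) {
    cnt <- 0L
    for (gi in g) if (gi == k) cnt <- cnt + 1L
    out[k] <- cnt / length(g)
  }
  out
}

oracle_transition <- function(g) {
  n <- length(g)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- numeric(3)
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    cnt <- 0L
    for (i in 1:(n - 1)) {
      if ((g[i] == a && g[i + 1] == b) || (g[i] == b && g[i + 1] == a)) {
        cnt <- cnt + 1L
      }
    }
    out[p] <- 100 * cnt / (n - 1)
  }
  out
}

oracle_distribution <- function(g) {
  n <- length(g)
  out <- numeric(15)
  for (k in 1:3) {
    pos <- integer(0)
    for (i in seq_len(n)) if (g[i] == k) pos <- c(pos, i)
    m <- length(pos)
    if (m == 0L) next
    targets <- c(1L, ceiling(0.25 * m), ceiling(0.50 * m),
                 ceiling(0.75 * m), m)
    for (q in 1:5) {
      out[(k - 1) * 5 + q] <- 100 * pos[max(1L, targets[q])] / n
    }
  }
  out
}

# direct double-loop transcription of the lag-covariance definition
oracle_auto_covariance <- function(v, max_lag = 30L) {
  n <- length(v)
  vbar <- sum(v) / n
  out <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    acc <- 0
    for (i in seq_len(n - lag)) {
      acc <- acc + (v[i] - vbar) * (v[i + lag] - vbar)
    }
    out[lag] <- acc / (n - lag)
  }
  out
}

random_protein <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# small deterministic separable toy problem for classifier tests
separable_toy <- function() {
  x <- cbind(c(1:10 / 10, 1:10 / 10 + 2),
             c(seq(-1, 1, length.out = 10), seq(-1, 1, length.out = 10)))
  y <- rep(c(0L, 1L), each = 10)
  list(x = x, y = y)
}
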