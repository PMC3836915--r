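# Independent oracles used to freeze expected values.

# Central finite differences of a scalar function.
numeric_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

# Naive step-pattern misfit count: explicit loops, no shared code with
# guttman_sort().  Rows by total (desc, then label), columns by total
# (desc, then label); a row with total k should have 1s in exactly the
# first k sorted columns.
oracle_guttman_misfits <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  rt <- numeric(nrow(m))
  ct <- numeric(ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    rt[i] <- rt[i] + m[i, j]
    ct[j] <- ct[j] + m[i, j]
  }
  ro <- order(-rt, rownames(m))
  co <- order(-ct, colnames(m))
  mis <- 0L
  for (i in ro) {
    k <- rt[i]
    for (jj in seq_along(co)) {
      expected <- if (jj <= k) 1 else 0
      if (m[i, co[jj]] != expected) mis <- mis + 1L
    }
  }
  mis
}

# Brute-force dot product by looping over attributes (independent of the
# design-vector machinery).
oracle_state_value <- function(levels, system, gamma) {
  total <- 0
  pos <- 0L
  for (i in seq_along(system$attributes)) {
    L <- system$n_levels[i]
    for (l in 2:L) {
      pos <- pos + 1L
      if (levels[i] == l) total <- total + gamma[pos]
    }
  }
  total
}
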