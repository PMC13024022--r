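# Independent brute-force oracles used to cross-check the pipeline.
# These deliberately re-derive each quantity from first principles
# (naive loops, path enumeration) rather than reusing package internals.

# wPLI by naive per-pair, per-sample loops on analytic signals
oracle_wpli <- function(z) {
  n <- nrow(z)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0
      den <- 0
      for (t in seq_len(ncol(z))) {
        im <- Im(z[i, t] * Conj(z[j, t]))
        num <- num + im
        den <- den + abs(im)
      }
      out[i, j] <- if (den > 0) abs(num) / den else 0
    }
  }
  out
}

# all-pairs shortest paths by Floyd-Warshall on a binary adjacency matrix
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  vals <- 1 / d[upper.tri(d)]
  mean(ifelse(is.finite(vals), vals, 0))
}

oracle_char_path_length <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v) & v > 0]
  if (length(v)) mean(v) else NA_real_
}

# betweenness by explicit enumeration of all simple shortest paths
# (exponential; only for small graphs)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  # count shortest paths between s and t passing through each vertex
  paths_between <- function(s, t) {
    # BFS-style enumeration of geodesics
    res <- list()
    grow <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ] > 0)) {
        if (d[s, w] == length(path) && d[w, t] == d[s, t] - length(path)) {
          grow(c(path, w))
        }
      }
    }
    grow(s)
    res
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      paths <- paths_between(s, t)
      if (!length(paths)) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(paths)
      }
    }
  }
  bc
}

# trapezoid rule by explicit summation
oracle_trapezoid <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# Mann-Whitney U by explicit pair counting
oracle_u_count <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Cliff's delta by dominance counting
oracle_cliffs_delta <- function(x, y) {
  gt <- lt <- 0
  for (xi in x) for (yj in y) {
    gt <- gt + (xi > yj)
    lt <- lt + (xi < yj)
  }
  abs(gt - lt) / (length(x) * length(y))
}

# small synthetic two-region series with a stochastic phase-lag bias
make_lagged_pair <- function(n, fs, freq, lag, noise = 0.5, seed = 1) {
  withr::with_seed(seed, {
    ph <- cumsum(rnorm(n, 0, 0.05))
    t <- seq_len(n) / fs
    x <- sin(2 * pi * freq * t + ph)
    y <- sin(2 * pi * freq * t + ph - lag)
    rbind(x + noise * rnorm(n), y + noise * rnorm(n))
  })
}
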