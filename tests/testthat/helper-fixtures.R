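# Shared fixtures and independent oracles for the test suite.

# memo store for expensive shared computations
.memo <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

# hand-built coherency_set with a constant complex rhat on every pair;
# test scaffolding for the network-aggregation layer
const_coherency_set <- function(labels, rhat_value, fs = 100, duration = 2,
                                freqs = c(40, 30, 20, 10, 5)) {
  nt <- round(fs * duration)
  ns <- length(freqs)
  time <- (seq_len(nt) - 1) / fs
  pairs <- utils::combn(sort(labels), 2, simplify = FALSE)
  maps <- lapply(pairs, function(p) {
    structure(
      list(rhat = matrix(rhat_value, ns, nt),
           valid = matrix(TRUE, ns, nt),
           n_epochs = 1L, scales = 6 / (2 * pi * freqs), freqs = freqs,
           fs = fs, time = time, coi = matrix(TRUE, ns, nt),
           pair = p, spec = NULL),
      class = "coherency_map")
  })
  names(maps) <- vapply(pairs, function(p) paste(p, collapse = "~"),
                        character(1))
  structure(list(maps = maps, labels = sort(labels),
                 spec = NULL, time = time, freqs = freqs, fs = fs),
            class = "coherency_set")
}

# hand-built mask set covering a coherency_set, all flags equal to `flag`
const_mask_set <- function(set, flag) {
  out <- lapply(set$maps, function(m) {
    structure(list(flags = matrix(flag, nrow(m$rhat), ncol(m$rhat)),
                   q = 0.95, B = 1L, measure = "iwtc_abs", pair = m$pair),
              class = "significance_mask")
  })
  class(out) <- "significance_mask_set"
  out
}

# quick snapshot from an edge table
snap <- function(nodes, ...) {
  ed <- tibble::tribble(...)
  network_snapshot(nodes, ed)
}

## ---- exhaustive shortest-path oracles (for graphs with <= ~7 nodes) ----

# all simple paths from s to t over directed weight matrix W (0 = no arc),
# distances = 1/weight
oracle_all_paths <- function(W, s, t) {
  n <- nrow(W)
  res <- list()
  walk <- function(path, dist) {
    v <- path[length(path)]
    if (v == t) {
      res[[length(res) + 1L]] <<- list(path = path, dist = dist)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !(u %in% path)) {
        walk(c(path, u), dist + 1 / W[v, u])
      }
    }
  }
  walk(s, 0)
  res
}

# betweenness by enumeration of all shortest paths (Freeman, weighted)
oracle_betweenness <- function(W) {
  n <- nrow(W)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- oracle_all_paths(W, s, t)
    if (!length(paths)) next
    dists <- vapply(paths, `[[`, numeric(1), "dist")
    dmin <- min(dists)
    shortest <- paths[dists <= dmin * (1 + 1e-12)]
    sigma <- length(shortest)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      sigma_v <- sum(vapply(shortest, function(p) v %in% p$path, logical(1)))
      bc[v] <- bc[v] + sigma_v / sigma
    }
  }
  bc
}

# harmonic closeness (outgoing): mean over targets of 1/shortest-distance
oracle_harmonic_out <- function(W) {
  n <- nrow(W)
  hc <- numeric(n)
  for (s in seq_len(n)) {
    acc <- 0
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- oracle_all_paths(W, s, t)
      if (length(paths)) {
        acc <- acc + 1 / min(vapply(paths, `[[`, numeric(1), "dist"))
      }
    }
    hc[s] <- acc / (n - 1)
  }
  hc
}

# random snapshot whose directed view is one arc per pair (plus optional
# reciprocal ties), for the centrality oracle property
random_digraph_snapshot <- function(n_nodes, p_edge = 0.7, p_tie = 0.15) {
  nodes <- letters[seq_len(n_nodes)]
  pairs <- utils::combn(nodes, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    if (stats::runif(1) > p_edge) return(NULL)
    dir <- if (stats::runif(1) < p_tie) 0 else sample(c(-1, 1), 1)
    tibble::tibble(from = p[1], to = p[2],
                   weight = stats::runif(1, 0.2, 1), direction = dir)
  })
  ed <- dplyr::bind_rows(rows)
  if (is.null(ed) || nrow(ed) == 0L) {
    ed <- tibble::tibble(from = nodes[1], to = nodes[2], weight = 0.5,
                         direction = 1)
  }
  network_snapshot(nodes, ed)
}

## ---- direct time-domain CWT / smoothing oracle ----

# direct per-bin summation with the time-sampled analytic Morlet; matches
# the FFT path when kernels decay inside the record
oracle_cwt <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / fs
  W <- matrix(0 + 0i, length(scales), n)
  for (s in seq_along(scales)) {
    sc <- scales[s]
    for (k in seq_len(n)) {
      dtau <- tt[k] - tt
      ker <- pi^(-1 / 4) / sqrt(sc * fs) *
        exp(1i * omega0 * dtau / sc) * exp(-dtau^2 / (2 * sc^2))
      W[s, k] <- sum(x * ker)
    }
  }
  W
}

oracle_smooth <- function(field, scales, fs, smooth_scales) {
  ns <- nrow(field); nt <- ncol(field)
  out <- field
  for (s in seq_len(ns)) {
    sig <- scales[s] * fs
    for (k in seq_len(nt)) {
      g <- exp(-((seq_len(nt) - k)^2) / (2 * sig^2))
      out[s, k] <- sum(field[s, ] * g) / sum(g)
    }
  }
  m <- smooth_scales
  h_lo <- (m - 1L) %/% 2L
  h_hi <- m - 1L - h_lo
  final <- out
  for (s in seq_len(ns)) {
    lo <- max(1L, s - h_lo); hi <- min(ns, s + h_hi)
    final[s, ] <- colMeans(out[lo:hi, , drop = FALSE])
  }
  final
}
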