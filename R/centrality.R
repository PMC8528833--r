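#' The ten supported centrality measures
#'
#' Undirected: weighted degree (strength), harmonic closeness, eigenvector.
#' Directed: weighted indegree, outdegree, in-/out-closeness (harmonic),
#' betweenness, HITS hubs, pagerank (damping 0.85). Path-based measures use
#' distance `1 / weight`; the harmonic closeness variant keeps disconnected
#' graphs well-defined (unreachable pairs contribute 0).
#'
#' @export
centrality_measures <- c("degree", "closeness", "eigenvector",
                         "indegree", "outdegree", "incloseness",
                         "outcloseness", "betweenness", "hubs", "pagerank")

power_iteration <- function(M, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(M)
  if (n == 0L || max(M) <= 0) return(rep(0, n))
  v <- rep(1, n)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(M %*% v)
    nrm <- max(abs(w))
    if (nrm <= 0) return(rep(0, n))
    w <- w / nrm
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v <- pmax(v, 0)
  if (max(v) > 0) v / max(v) else v
}

weight_matrix <- function(snapshot, directed = FALSE, tie_tol = 1e-6) {
  n <- length(snapshot$nodes)
  W <- matrix(0, n, n, dimnames = list(snapshot$nodes, snapshot$nodes))
  ed <- snapshot$edges
  for (r in seq_len(nrow(ed))) {
    i <- ed$from[r]; j <- ed$to[r]
    if (!directed) {
      W[i, j] <- W[i, j] + ed$weight[r]
      W[j, i] <- W[j, i] + ed$weight[r]
    } else if (abs(ed$direction[r]) <= tie_tol) {
      W[i, j] <- W[i, j] + ed$weight[r]
      W[j, i] <- W[j, i] + ed$weight[r]
    } else if (ed$direction[r] > 0) {
      W[j, i] <- W[j, i] + ed$weight[r]
    } else {
      W[i, j] <- W[i, j] + ed$weight[r]
    }
  }
  W
}

#' Weighted centrality of every node in a snapshot
#'
#' @param snapshot a `network_snapshot`.
#' @param measure one of [centrality_measures].
#' @param tie_tol direction-score magnitude below which an edge is treated as
#'   reciprocal in the directed view.
#' @return Tibble with `node`, `measure`, `value`. Isolated nodes get 0 for
#'   strength- and path-based measures; pagerank sums to 1; eigenvector and
#'   hub scores are normalized to unit maximum.
#' @export
compute_centrality <- function(snapshot, measure, tie_tol = 1e-6) {
  stopifnot(inherits(snapshot, "network_snapshot"))
  if (!measure %in% centrality_measures) {
    abort_glue("unknown measure '", measure, "'. Valid measures: ",
               paste(centrality_measures, collapse = ", "), ".")
  }
  nodes <- snapshot$nodes
  n <- length(nodes)
  if (nrow(snapshot$edges) == 0L) {
    return(tibble::tibble(node = nodes, measure = measure,
                          value = rep(0, n)))
  }
  directed <- measure %in% c("indegree", "outdegree", "incloseness",
                             "outcloseness", "betweenness", "hubs",
                             "pagerank")
  g <- snapshot_igraph(snapshot, directed = directed, tie_tol = tie_tol)
  w <- igraph::E(g)$weight
  val <- switch(
    measure,
    degree = igraph::strength(g, mode = "all"),
    indegree = igraph::strength(g, mode = "in"),
    outdegree = igraph::strength(g, mode = "out"),
    closeness = igraph::harmonic_centrality(g, mode = "all", weights = 1 / w,
                                            normalized = TRUE),
    incloseness = igraph::harmonic_centrality(g, mode = "in", weights = 1 / w,
                                              normalized = TRUE),
    outcloseness = igraph::harmonic_centrality(g, mode = "out",
                                               weights = 1 / w,
                                               normalized = TRUE),
    betweenness = igraph::betweenness(g, directed = TRUE, weights = 1 / w),
    eigenvector = power_iteration(weight_matrix(snapshot, directed = FALSE)),
    hubs = {
      A <- weight_matrix(snapshot, directed = TRUE, tie_tol = tie_tol)
      power_iteration(A %*% t(A))
    },
    pagerank = igraph::page_rank(g, damping = 0.85, weights = w)$vector
  )
  val <- as.numeric(val)[match(nodes, if (is.null(names(val)))
    nodes else names(val))]
  val[is.na(val)] <- 0
  tibble::tibble(node = nodes, measure = measure, value = val)
}

#' Centrality tracked across a dynamic network
#'
#' Computes one centrality measure per snapshot of a [build_dynamic_network()]
#' result. Windows with no edges yield zeros for every node.
#'
#' @param dyn a `dynamic_network`.
#' @param measure one of [centrality_measures].
#' @return An object of class `dynamic_centrality`: `series` (node x window
#'   matrix), `mean_series` (per-window mean over nodes), `w`, `measure`,
#'   `windows`.
#' @export
dynamic_centrality <- function(dyn, measure) {
  stopifnot(inherits(dyn, "dynamic_network"))
  cols <- purrr::map(dyn$snapshots, function(s) {
    if (nrow(s$edges) == 0L) {
      stats::setNames(rep(0, length(dyn$nodes)), dyn$nodes)
    } else {
      tb <- compute_centrality(s, measure)
      stats::setNames(tb$value, tb$node)[dyn$nodes]
    }
  })
  series <- do.call(cbind, cols)
  dimnames(series) <- list(dyn$nodes, paste0("w", seq_along(dyn$snapshots)))
  structure(
    list(series = series, mean_series = colMeans(series), w = dyn$w,
         measure = measure, windows = dyn$windows),
    class = "dynamic_centrality"
  )
}

#' @export
print.dynamic_centrality <- function(x, ...) {
  cat("<dynamic_centrality> ", x$measure, " over ", ncol(x$series),
      " window(s) x ", nrow(x$series), " node(s), w = ", x$w, " s\n",
      sep = "")
  invisible(x)
}

#' Characteristic centrality: PCA ranking of centrality measures
#'
#' Treats the centrality measures as variables over the nodes, z-scores each
#' measure (their scales are incommensurable), and runs a PCA via singular
#' value decomposition. The contribution of measure `m` to component `k` is
#' `100 * loading(m, k)^2 / sum_m loading(m, k)^2`; measures are ranked by
#' their contribution to PC1, the component carrying most of the network's
#' variance. The top-ranked measures are the ones that summarise this
#' particular network best.
#'
#' @param snapshot a `network_snapshot` with >= 3 nodes.
#' @param measures measures to include (default all ten).
#' @param n_components number of components reported (default 3, capped by
#'   the data rank).
#' @return An object of class `characteristic_centrality`: `contributions`
#'   (tibble `measure`, `component`, `contribution` in percent),
#'   `variance_fraction` (per reported component), `ranking` (measures by
#'   PC1 contribution), `dropped` (constant measures removed), `table`
#'   (node x measure input matrix).
#' @export
characteristic_centrality <- function(snapshot,
                                      measures = centrality_measures,
                                      n_components = 3L) {
  stopifnot(inherits(snapshot, "network_snapshot"))
  if (length(snapshot$nodes) < 3L) {
    abort_glue("characteristic centrality needs >= 3 nodes.")
  }
  X <- vapply(measures,
              function(m) compute_centrality(snapshot, m)$value,
              numeric(length(snapshot$nodes)))
  rownames(X) <- snapshot$nodes
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds <= .Machine$double.eps^0.5]
  if (length(dropped)) {
    warning("dropping constant measure(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  keep <- setdiff(colnames(X), dropped)
  if (length(keep) < 2L) {
    abort_glue("need >= 2 non-constant measures for the PCA.")
  }
  Z <- scale(X[, keep, drop = FALSE])
  sv <- svd(Z)
  k <- min(n_components, length(sv$d), nrow(Z) - 1L)
  V <- sv$v[, seq_len(k), drop = FALSE]
  contrib <- 100 * sweep(V^2, 2, colSums(V^2), "/")
  dimnames(contrib) <- list(keep, paste0("PC", seq_len(k)))
  varfrac <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  ranking <- keep[order(-contrib[, 1], keep)]
  long <- tibble::as_tibble(as.table(contrib), .name_repair = "minimal")
  names(long) <- c("measure", "component", "contribution")
  structure(
    list(contributions = tibble::as_tibble(long),
         variance_fraction = stats::setNames(varfrac, paste0("PC",
                                                             seq_len(k))),
         ranking = ranking, dropped = dropped, table = X),
    class = "characteristic_centrality"
  )
}

#' @export
print.characteristic_centrality <- function(x, ...) {
  cat("<characteristic_centrality> ranking by PC1 contribution (",
      round(100 * x$variance_fraction[1], 1), "% of variance):\n", sep = "")
  cat("  ", paste(utils::head(x$ranking, 5), collapse = " > "), "\n",
      sep = "")
  invisible(x)
}
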