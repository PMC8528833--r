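#' Static network snapshot from coherency maps
#'
#' Aggregates connectivity into a weighted graph over the channels: per pair,
#' the edge weight is the mean `|Im(R)|` over the bins inside the requested
#' time-frequency window (restricted to significant bins when a mask is
#' given, and always to the cone of influence), and the direction score is
#' the mean sign of `Im(R)` over the same bins. Pairs with no qualifying bins
#' get no edge.
#'
#' @param maps a `coherency_set` from [all_pairs_maps()].
#' @param mask optional `significance_mask_set` from [significance_masks()].
#' @param t_window,f_window numeric `[lo, hi]` (s relative to the event, Hz),
#'   or `NULL` for the full axis ("Time: Full" / "Frequency: Full").
#'
#' @return An object of class `network_snapshot`: `nodes`, `edges` (tibble
#'   `from`, `to`, `weight`, `direction` with `from < to` lexicographically;
#'   `direction > 0` means `to` leads `from`, i.e. information flows
#'   `to -> from`), and the window.
#' @export
build_snapshot <- function(maps, mask = NULL, t_window = NULL,
                           f_window = NULL) {
  stopifnot(inherits(maps, "coherency_set"))
  if (!is.null(mask) && !inherits(mask, "significance_mask_set")) {
    abort_glue("`mask` must come from significance_masks() (or be NULL).")
  }
  rows <- purrr::map(names(maps$maps), function(key) {
    m <- maps$maps[[key]]
    sel <- window_bins(m, t_window, f_window) & m$coi & m$valid
    if (!is.null(mask)) {
      fl <- mask[[key]]
      if (is.null(fl)) abort_glue("mask is missing pair '", key, "'.")
      sel <- sel & fl$flags
    }
    if (!any(sel)) return(NULL)
    iw <- Im(m$rhat)[sel]
    w <- mean(abs(iw))
    if (w <= 0) return(NULL)   # a zero-strength pair is no edge
    tibble::tibble(from = m$pair[1], to = m$pair[2],
                   weight = w, direction = mean(sign(iw)))
  })
  edges <- dplyr::bind_rows(rows)
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric(), direction = numeric())
  }
  structure(
    list(nodes = maps$labels, edges = edges,
         t_window = t_window %||% range(maps$time),
         f_window = f_window %||% range(maps$freqs),
         significant_only = !is.null(mask)),
    class = "network_snapshot"
  )
}

#' Construct a snapshot directly from an edge table
#'
#' Mainly for fixtures and for re-importing exported edge lists.
#'
#' @param nodes character vector of node labels.
#' @param edges tibble/data frame with `from`, `to`, `weight` and optionally
#'   `direction` (default 0).
#' @param t_window,f_window window metadata.
#' @return A `network_snapshot`.
#' @export
network_snapshot <- function(nodes, edges, t_window = c(NA_real_, NA_real_),
                             f_window = c(NA_real_, NA_real_)) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    abort_glue("`edges` needs columns from, to, weight.")
  }
  if (!"direction" %in% names(edges)) edges$direction <- 0
  if (any(edges$from == edges$to)) abort_glue("self-edges are not allowed.")
  if (any(edges$weight < 0)) abort_glue("edge weights must be >= 0.")
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) {
    abort_glue("edge endpoints not in `nodes`: ", paste(bad, collapse = ", "))
  }
  structure(
    list(nodes = as.character(nodes), edges = edges, t_window = t_window,
         f_window = f_window, significant_only = FALSE),
    class = "network_snapshot"
  )
}

#' @export
print.network_snapshot <- function(x, ...) {
  cat("<network_snapshot> ", length(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s)", if (x$significant_only) ", significant bins only", "\n",
      sep = "")
  invisible(x)
}

#' Dynamic network: a sequence of snapshots over sliding time windows
#'
#' Divides the maps' time span `T` into `n = ceiling(T / w)` fixed windows of
#' length `w` seconds (the last may be shorter) and builds one snapshot per
#' window; the node set is constant across snapshots.
#'
#' @param maps a `coherency_set`.
#' @param mask optional `significance_mask_set`.
#' @param w window size in seconds (`0 < w <= T`).
#' @param f_window optional frequency window `[lo, hi]` Hz.
#'
#' @return An object of class `dynamic_network`: `snapshots` (list),
#'   `w`, `windows` (tibble of window bounds), `nodes`.
#' @export
build_dynamic_network <- function(maps, mask = NULL, w, f_window = NULL) {
  stopifnot(inherits(maps, "coherency_set"))
  check_number(w, "w", positive = TRUE)
  nt <- length(maps$time)
  T_span <- nt / maps$fs
  if (w > T_span + 1e-9) abort_glue("`w` exceeds the record span ", T_span,
                                    " s.")
  n_win <- ceiling(T_span / w - 1e-9)
  # assign each time bin to a window on the sample grid
  widx <- pmin(floor((seq_len(nt) - 1) / (w * maps$fs)) + 1L, n_win)
  snaps <- vector("list", n_win)
  bounds <- matrix(NA_real_, n_win, 2)
  for (k in seq_len(n_win)) {
    tk <- range(maps$time[widx == k])
    bounds[k, ] <- tk
    snaps[[k]] <- build_snapshot(maps, mask, t_window = tk,
                                 f_window = f_window)
  }
  structure(
    list(snapshots = snaps, w = w, nodes = maps$labels,
         windows = tibble::tibble(window = seq_len(n_win),
                                  t_start = bounds[, 1], t_end = bounds[, 2])),
    class = "dynamic_network"
  )
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("<dynamic_network> ", length(x$snapshots), " snapshot(s), w = ", x$w,
      " s, ", length(x$nodes), " node(s)\n", sep = "")
  invisible(x)
}

#' Global Microscale Connectivity
#'
#' Scalar summary of a snapshot: the mean edge weight over all `C(n, 2)` node
#' pairs. By default absent edges count as zero, making the measure sensitive
#' to network density and comparable across subjects with different sparsity.
#'
#' @param snapshot a `network_snapshot` with >= 2 nodes.
#' @param absent_as_zero count missing pairs as weight 0 (default) rather
#'   than averaging over existing edges only.
#' @return A scalar in `[0, 1]`.
#' @export
global_microscale_connectivity <- function(snapshot, absent_as_zero = TRUE) {
  stopifnot(inherits(snapshot, "network_snapshot"))
  n <- length(snapshot$nodes)
  if (n < 2L) abort_glue("GMC needs >= 2 nodes.")
  if (nrow(snapshot$edges) == 0L) return(0)
  if (absent_as_zero) {
    sum(snapshot$edges$weight) / choose(n, 2)
  } else {
    mean(snapshot$edges$weight)
  }
}

snapshot_igraph <- function(snapshot, directed = FALSE, tie_tol = 1e-6) {
  ed <- snapshot$edges
  if (!directed) {
    g <- igraph::graph_from_data_frame(
      ed[, c("from", "to", "weight")], directed = FALSE,
      vertices = data.frame(name = snapshot$nodes))
    return(g)
  }
  # orient by the direction score: direction > 0 means `to` leads `from`
  # (flow to -> from); near-zero scores become reciprocal arcs.
  src <- character(0); dst <- character(0); wgt <- numeric(0)
  for (r in seq_len(nrow(ed))) {
    if (abs(ed$direction[r]) <= tie_tol) {
      src <- c(src, ed$from[r], ed$to[r])
      dst <- c(dst, ed$to[r], ed$from[r])
      wgt <- c(wgt, ed$weight[r], ed$weight[r])
    } else if (ed$direction[r] > 0) {
      src <- c(src, ed$to[r]); dst <- c(dst, ed$from[r])
      wgt <- c(wgt, ed$weight[r])
    } else {
      src <- c(src, ed$from[r]); dst <- c(dst, ed$to[r])
      wgt <- c(wgt, ed$weight[r])
    }
  }
  igraph::graph_from_data_frame(
    data.frame(from = src, to = dst, weight = wgt), directed = TRUE,
    vertices = data.frame(name = snapshot$nodes))
}

#' Force-directed snapshot layout
#'
#' Fruchterman-Reingold layout (attraction proportional to edge weight),
#' deterministic under the seed, with coordinates centred at the origin and
#' scaled to a unit box (maximum extent 1).
#'
#' @param snapshot a `network_snapshot` with >= 1 node.
#' @param seed integer seed.
#' @param iterations FR iterations (default 500).
#' @return Tibble with `node`, `x`, `y`.
#' @export
force_layout <- function(snapshot, seed = 1L, iterations = 500L) {
  stopifnot(inherits(snapshot, "network_snapshot"))
  n <- length(snapshot$nodes)
  if (n < 1L) abort_glue("need >= 1 node.")
  if (n == 1L) {
    return(tibble::tibble(node = snapshot$nodes, x = 0, y = 0))
  }
  g <- snapshot_igraph(snapshot, directed = FALSE)
  xy <- withr::with_seed(as.integer(seed), {
    igraph::layout_with_fr(g, niter = as.integer(iterations),
                           weights = igraph::E(g)$weight %||% NULL)
  })
  xy <- sweep(xy, 2, colMeans(xy))
  ext <- max(abs(xy), 1e-12)
  xy <- xy / (2 * ext)
  tibble::tibble(node = snapshot$nodes, x = xy[, 1], y = xy[, 2])
}

#' Layered (hierarchical) layout of a directed snapshot
#'
#' Draws the oriented network in horizontal layers with edges generally
#' pointing downwards: greedy weighted cycle-breaking (the removed back edges
#' are reported as feedback, never an error), longest-path layering of the
#' remaining DAG, then a few barycenter sweeps to order nodes within layers.
#' Crossing minimisation is NP-hard, so the ordering is an explicit
#' heuristic. Edges whose `|direction|` falls below `tie_tol` carry no
#' orientation and are excluded from layering.
#'
#' @param snapshot a `network_snapshot`.
#' @param tie_tol direction-score magnitude below which an edge counts as
#'   undirected.
#' @param sweeps barycenter ordering sweeps.
#' @return A list with `layers` (tibble `node`, `layer`, `order`) and
#'   `feedback` (tibble of removed back edges `from`, `to`, `weight`). Every
#'   retained directed edge points to a strictly deeper layer.
#' @export
layered_layout <- function(snapshot, tie_tol = 1e-6, sweeps = 4L) {
  stopifnot(inherits(snapshot, "network_snapshot"))
  ed <- snapshot$edges[abs(snapshot$edges$direction) > tie_tol, , drop = FALSE]
  src <- ifelse(ed$direction > 0, ed$to, ed$from)
  dst <- ifelse(ed$direction > 0, ed$from, ed$to)
  arcs <- tibble::tibble(from = src, to = dst, weight = ed$weight)
  nodes <- snapshot$nodes
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  fas <- igraph::feedback_arc_set(g, weights = igraph::E(g)$weight,
                                  algo = "approx_eades")
  feedback <- if (length(fas)) {
    fe <- igraph::ends(g, fas)
    tibble::tibble(from = fe[, 1], to = fe[, 2],
                   weight = igraph::E(g)$weight[as.integer(fas)])
  } else {
    tibble::tibble(from = character(), to = character(), weight = numeric())
  }
  gd <- igraph::delete_edges(g, fas)
  topo <- igraph::topo_sort(gd, mode = "out")
  layer <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (v in names(topo)) {
    preds <- names(igraph::neighbors(gd, v, mode = "in"))
    if (length(preds)) layer[v] <- max(layer[preds]) + 1L
  }
  # barycenter ordering within layers
  ord <- stats::setNames(rank(layer, ties.method = "first"), nodes)
  adj <- igraph::as_adjacency_matrix(gd, sparse = FALSE)
  for (s in seq_len(sweeps)) {
    for (l in sort(unique(layer))) {
      members <- nodes[layer == l]
      if (length(members) < 2L) next
      bc <- vapply(members, function(v) {
        nb <- c(names(which(adj[, v] > 0)), names(which(adj[v, ] > 0)))
        nb <- nb[layer[nb] != l]
        if (length(nb)) mean(ord[nb]) else ord[v]
      }, numeric(1))
      ord[members] <- rank(bc, ties.method = "first")
    }
  }
  list(layers = tibble::tibble(node = nodes,
                               layer = as.integer(layer[nodes]),
                               order = as.integer(ord[nodes])),
       feedback = feedback)
}
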