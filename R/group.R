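#' Stack subject-level snapshots into a subjects x pairs matrix
#'
#' Aligns the connectivity of several subjects over a common channel set:
#' row `s`, column `p` holds subject `s`'s edge weight for channel pair `p`
#' (all `C(n, 2)` pairs; absent edges are 0). All subjects must share the
#' node set — a mismatch is an error naming the offending subject.
#'
#' @param snapshots list of `network_snapshot` objects, one per subject.
#' @param subject_ids optional character ids (default `S1`, `S2`, ...).
#' @return An object of class `group_stack`: matrix `G`, `subject_ids`,
#'   `pairs`, `nodes`.
#' @export
group_stack <- function(snapshots, subject_ids = NULL) {
  if (!length(snapshots)) abort_glue("need >= 1 subject snapshot.")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_along(snapshots))
  nodes <- sort(snapshots[[1]]$nodes)
  pairs_mat <- utils::combn(nodes, 2)
  pairs <- pair_key(pairs_mat[1, ], pairs_mat[2, ])
  G <- matrix(0, length(snapshots), length(pairs),
              dimnames = list(subject_ids, pairs))
  for (s in seq_along(snapshots)) {
    sn <- snapshots[[s]]
    if (!inherits(sn, "network_snapshot")) {
      abort_glue("snapshot ", s, " is not a network_snapshot.")
    }
    if (!identical(sort(sn$nodes), nodes)) {
      abort_glue("subject '", subject_ids[s],
                 "' has a different channel set.")
    }
    if (nrow(sn$edges)) {
      key <- pair_key(sn$edges$from, sn$edges$to)
      G[s, key] <- sn$edges$weight
    }
  }
  structure(list(G = G, subject_ids = subject_ids, pairs = pairs,
                 nodes = nodes),
            class = "group_stack")
}

#' @export
print.group_stack <- function(x, ...) {
  cat("<group_stack> ", nrow(x$G), " subject(s) x ", ncol(x$G),
      " channel pair(s)\n", sep = "")
  invisible(x)
}

#' Grand-average connectivity across subjects
#'
#' @param stack a `group_stack`.
#' @return Tibble with `pair` and `weight` (column-wise mean across
#'   subjects).
#' @export
grand_average <- function(stack) {
  stopifnot(inherits(stack, "group_stack"))
  tibble::tibble(pair = stack$pairs, weight = colMeans(stack$G))
}

#' PCA network modules across subjects
#'
#' Identifies subnetworks that explain the group's connectivity variance:
#' each subject's own mean connectivity is subtracted (row-centering — no
#' variance scaling), then a singular value decomposition yields up to
#' `min(3, n - 1)` components. Each component's loading vector, down-projected
#' onto the channel pairs, is a network module; its squared singular value
#' over the total is the fraction of group variance it accounts for. Loading
#' signs are fixed so the largest-magnitude entry is positive, making module
#' maps reproducible under subject permutation.
#'
#' @param stack a `group_stack` with >= 2 subjects.
#' @return An object of class `pca_modules`: `loadings` (pairs x components,
#'   unit-norm columns), `variance_fraction`, `scores` (subjects x
#'   components), `pairs`.
#' @export
network_modules_pca <- function(stack) {
  stopifnot(inherits(stack, "group_stack"))
  n <- nrow(stack$G)
  if (n < 2L) abort_glue("PCA modules need >= 2 subjects.")
  Xc <- stack$G - rowMeans(stack$G)
  total <- sum(Xc^2)
  between <- sum(sweep(Xc, 2, colMeans(Xc))^2)
  if (total <= .Machine$double.eps ||
      between <= 1e-12 * max(total, 1)) {
    abort_glue("no between-subject variance after subject-mean centering ",
               "(identical subjects).")
  }
  sv <- svd(Xc)
  k <- min(3L, n - 1L, sum(sv$d > sv$d[1] * 1e-12))
  V <- sv$v[, seq_len(k), drop = FALSE]
  U <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  flip <- vapply(seq_len(k), function(c) {
    sign(V[which.max(abs(V[, c])), c])
  }, numeric(1))
  V <- sweep(V, 2, flip, "*")
  U <- sweep(U, 2, flip, "*")
  rownames(V) <- stack$pairs
  colnames(V) <- paste0("PC", seq_len(k))
  scores <- sweep(U, 2, d, "*")
  dimnames(scores) <- list(stack$subject_ids, colnames(V))
  structure(
    list(loadings = V,
         variance_fraction = stats::setNames(d^2 / sum(sv$d^2), colnames(V)),
         scores = scores, pairs = stack$pairs, nodes = stack$nodes),
    class = "pca_modules"
  )
}

#' @export
print.pca_modules <- function(x, ...) {
  cat("<pca_modules> ", ncol(x$loadings), " component(s); variance: ",
      paste(round(100 * x$variance_fraction, 1), "%", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Effect size of a group difference in a scalar network measure
#'
#' Cohen's d with pooled standard deviation (`n - 1` denominators); the sign
#' convention is group A minus group B. Hedges' small-sample correction is
#' available via `hedges = TRUE`.
#'
#' @param gmc_a,gmc_b numeric vectors of per-subject values (each >= 2).
#' @param hedges apply Hedges' g correction.
#' @return An object of class `effect_size`: list with `d`, `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`, `method`.
#' @export
group_effect_size <- function(gmc_a, gmc_b, hedges = FALSE) {
  gmc_a <- as.numeric(gmc_a); gmc_b <- as.numeric(gmc_b)
  if (length(gmc_a) < 2L || length(gmc_b) < 2L) {
    abort_glue("each group needs >= 2 values.")
  }
  n1 <- length(gmc_a); n2 <- length(gmc_b)
  s1 <- stats::sd(gmc_a); s2 <- stats::sd(gmc_b)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp <= 0) abort_glue("pooled standard deviation is zero.")
  d <- (mean(gmc_a) - mean(gmc_b)) / sp
  method <- "cohen_d"
  if (hedges) {
    d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
    method <- "hedges_g"
  }
  structure(
    list(d = d, mean_a = mean(gmc_a), mean_b = mean(gmc_b),
         sd_a = s1, sd_b = s2, n_a = n1, n_b = n2, method = method),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat("<effect_size> ", x$method, " = ", round(x$d, 3), " (A: ",
      round(x$mean_a, 4), " +/- ", round(x$sd_a, 4), ", n = ", x$n_a,
      "; B: ", round(x$mean_b, 4), " +/- ", round(x$sd_b, 4), ", n = ",
      x$n_b, ")\n", sep = "")
  invisible(x)
}
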