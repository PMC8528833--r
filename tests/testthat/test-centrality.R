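test_that("strength and pagerank recover textbook symmetric cases", {
  # unit-weight star S4: hub degree 3, leaves 1
  star <- snap(c("h", "l1", "l2", "l3"),
               ~from, ~to, ~weight, ~direction,
               "h", "l1", 1, 0, "h", "l2", 1, 0, "h", "l3", 1, 0)
  deg <- compute_centrality(star, "degree")
  expect_equal(deg$value[deg$node == "h"], 3)
  expect_equal(deg$value[deg$node != "h"], rep(1, 3))

  # unit-weight directed 3-cycle: pagerank 1/3 each
  cyc <- snap(c("a", "b", "c"),
              ~from, ~to, ~weight, ~direction,
              "a", "b", 1, -1,
              "b", "c", 1, -1,
              "a", "c", 1,  1)
  pr <- compute_centrality(cyc, "pagerank")
  expect_equal(pr$value, rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(pr$value), 1, tolerance = 1e-9)

  expect_error(compute_centrality(star, "katz"), "Valid measures")
})

test_that("betweenness and closeness match exhaustive-path oracles", {
  withr::with_seed(60, {
    for (rep in 1:30) {
      n <- sample(3:6, 1)
      s <- random_digraph_snapshot(n)
      W <- microcoh:::weight_matrix(s, directed = TRUE)
      bc <- compute_centrality(s, "betweenness")
      expect_equal(bc$value, oracle_betweenness(W), tolerance = 1e-9)
      oc <- compute_centrality(s, "outcloseness")
      expect_equal(oc$value, oracle_harmonic_out(W), tolerance = 1e-9)
      ic <- compute_centrality(s, "incloseness")
      expect_equal(ic$value, oracle_harmonic_out(t(W)), tolerance = 1e-9)
    }
  })
})

test_that("rankings are invariant to a global rescaling of edge weights", {
  withr::with_seed(61, {
    s <- random_digraph_snapshot(6, p_edge = 0.9)
  })
  s_scaled <- s
  s_scaled$edges$weight <- s$edges$weight * 7.3
  for (meas in c("pagerank", "eigenvector", "hubs", "betweenness")) {
    v1 <- compute_centrality(s, meas)$value
    v2 <- compute_centrality(s_scaled, meas)$value
    expect_equal(rank(v1), rank(v2), info = meas)
  }
})

test_that("degree splits into in- plus out-degree under reciprocal arcs", {
  withr::with_seed(62, {
    s <- random_digraph_snapshot(5, p_edge = 0.9, p_tie = 1)  # all ties
  })
  deg <- compute_centrality(s, "degree")$value
  ind <- compute_centrality(s, "indegree")$value
  outd <- compute_centrality(s, "outdegree")$value
  expect_equal(ind + outd, 2 * deg, tolerance = 1e-12)
  expect_equal(ind, outd, tolerance = 1e-12)
})

test_that("power-iteration eigenvector and hub scores agree with igraph", {
  withr::with_seed(63, {
    s <- random_digraph_snapshot(6, p_edge = 0.85)
  })
  ev <- compute_centrality(s, "eigenvector")
  g <- microcoh:::snapshot_igraph(s, directed = FALSE)
  ref <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  expect_equal(ev$value, as.numeric(ref[ev$node]), tolerance = 1e-6)

  hb <- compute_centrality(s, "hubs")
  gd <- microcoh:::snapshot_igraph(s, directed = TRUE)
  ref_h <- igraph::hits_scores(gd, weights = igraph::E(gd)$weight)$hub
  expect_equal(hb$value, as.numeric(ref_h[hb$node]), tolerance = 1e-6)
})

test_that("dynamic centrality tracks windowed structure exactly", {
  set <- const_coherency_set(c("a", "b", "h"), rhat_value = 0 + 0i,
                             fs = 100, duration = 2)
  set$maps[["a~b"]]$rhat[] <- 0 + 0.5i
  # edge to h only in window 3 of 4
  w3 <- set$time >= 1.0 & set$time < 1.5
  set$maps[["a~h"]]$rhat[, w3] <- 0 + 0.4i
  dyn <- build_dynamic_network(set, w = 0.5)
  dc <- dynamic_centrality(dyn, "degree")
  expect_equal(unname(dc$series["h", ]), c(0, 0, 0.4, 0))
  expect_equal(unname(dc$mean_series), unname(colMeans(dc$series)))

  # time-invariant network: constant series
  set2 <- const_coherency_set(c("a", "b"), rhat_value = 0 + 0.3i,
                              fs = 100, duration = 2)
  dc2 <- dynamic_centrality(build_dynamic_network(set2, w = 0.5), "degree")
  expect_true(all(abs(dc2$series - dc2$series[, 1]) < 1e-12))
})

test_that("characteristic centrality normalizes and ranks contributions", {
  withr::with_seed(64, {
    s <- random_digraph_snapshot(6, p_edge = 0.9)
  })
  cc <- characteristic_centrality(s)
  sums <- tapply(cc$contributions$contribution,
                 cc$contributions$component, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  expect_true(all(cc$variance_fraction >= 0 & cc$variance_fraction <= 1))
  expect_identical(cc$ranking[1],
                   cc$contributions$measure[
                     cc$contributions$component == "PC1"][
                       which.max(cc$contributions$contribution[
                         cc$contributions$component == "PC1"])])

  two <- snap(c("a", "b"), ~from, ~to, ~weight, ~direction, "a", "b", 1, 0)
  expect_error(characteristic_centrality(two), ">= 3 nodes")
})

test_that("collinear measures share PC1; an independent one loads later", {
  # two triangles joined via the low-degree cut vertex g: on an all-
  # reciprocal graph indegree and outdegree are exactly collinear, while g
  # gives betweenness its own, degree-independent variation
  s <- snap(c("a", "b", "c", "d", "e", "f", "g"),
            ~from, ~to, ~weight, ~direction,
            "a", "b", 1, 0, "a", "c", 1, 0, "b", "c", 1, 0,
            "c", "g", 1, 0, "g", "d", 1, 0,
            "d", "e", 1, 0, "d", "f", 1, 0, "e", "f", 1, 0)
  cc <- characteristic_centrality(
    s, measures = c("indegree", "outdegree", "betweenness"))
  pc1 <- cc$contributions[cc$contributions$component == "PC1", ]
  c_in <- pc1$contribution[pc1$measure == "indegree"]
  c_out <- pc1$contribution[pc1$measure == "outdegree"]
  c_btw <- pc1$contribution[pc1$measure == "betweenness"]
  expect_equal(c_in, c_out, tolerance = 1e-9)
  expect_lt(c_btw, c_in)
  pc2 <- cc$contributions[cc$contributions$component == "PC2", ]
  expect_identical(pc2$measure[which.max(pc2$contribution)], "betweenness")
  expect_gt(max(pc2$contribution), 50)
})
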