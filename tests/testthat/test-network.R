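test_that("snapshot aggregation averages |IWTC| over the targeted window", {
  set <- const_coherency_set(c("a", "b", "c"), rhat_value = 0 + 0.4i)
  sn <- build_snapshot(set)
  expect_equal(nrow(sn$edges), 3)
  expect_equal(sn$edges$weight, rep(0.4, 3))
  expect_equal(sn$edges$direction, rep(1, 3))

  # all-false mask: nodes remain, edges vanish
  sn0 <- build_snapshot(set, mask = const_mask_set(set, FALSE))
  expect_equal(length(sn0$nodes), 3)
  expect_equal(nrow(sn0$edges), 0)
  expect_true(sn0$significant_only)

  # full-window weight equals the bin-count-weighted mean of two halves
  half1 <- build_snapshot(set, t_window = c(0, 0.995))
  half2 <- build_snapshot(set, t_window = c(1.0, 2))
  n1 <- sum(set$time >= 0 & set$time <= 0.995)
  n2 <- sum(set$time >= 1.0 & set$time <= 2)
  full <- build_snapshot(set, t_window = c(0, 2))
  expect_equal(full$edges$weight[1],
               (n1 * half1$edges$weight[1] + n2 * half2$edges$weight[1]) /
                 (n1 + n2),
               tolerance = 1e-12)

  expect_error(build_snapshot(set, t_window = c(90, 99)), "window")
})

test_that("dynamic networks split the span into ceiling(T/w) snapshots", {
  set <- const_coherency_set(c("a", "b"), rhat_value = 0 + 0.3i,
                             fs = 100, duration = 2)
  dyn <- build_dynamic_network(set, w = 0.5)
  expect_length(dyn$snapshots, 4)
  expect_equal(dyn$windows$window, 1:4)

  # w = T: single snapshot identical to the full-window snapshot
  dyn1 <- build_dynamic_network(set, w = 2)
  expect_length(dyn1$snapshots, 1)
  full <- build_snapshot(set)
  expect_equal(dyn1$snapshots[[1]]$edges$weight, full$edges$weight)

  expect_error(build_dynamic_network(set, w = 0), "w")
  expect_error(build_dynamic_network(set, w = 5), "span")
})

test_that("an edge present only late in the record appears only in late windows", {
  set <- const_coherency_set(c("a", "b"), rhat_value = 0 + 0i,
                             fs = 100, duration = 2)
  # inject coupling only in the second half
  late <- set$time >= 1
  set$maps[["a~b"]]$rhat[, late] <- 0 + 0.5i
  dyn <- build_dynamic_network(set, w = 0.5)
  n_edges <- vapply(dyn$snapshots, function(s) nrow(s$edges), integer(1))
  expect_equal(n_edges, c(0L, 0L, 1L, 1L))
})

test_that("global microscale connectivity matches its definition", {
  s_all <- snap(c("a", "b", "c"),
                ~from, ~to, ~weight, ~direction,
                "a", "b", 0.7, 0,
                "a", "c", 0.7, 0,
                "b", "c", 0.7, 0)
  expect_equal(global_microscale_connectivity(s_all), 0.7)

  # half the pairs at 0.8, half absent
  s_half <- snap(c("a", "b", "c", "d"),
                 ~from, ~to, ~weight, ~direction,
                 "a", "b", 0.8, 0,
                 "a", "c", 0.8, 0,
                 "a", "d", 0.8, 0)
  expect_equal(global_microscale_connectivity(s_half), 0.4)
  expect_equal(global_microscale_connectivity(s_half, absent_as_zero = FALSE),
               0.8)
  expect_error(
    global_microscale_connectivity(network_snapshot("a", tibble::tibble(
      from = character(), to = character(), weight = numeric()))),
    ">= 2 nodes")
})

test_that("force layout is seeded, normalized and symmetric for a clique", {
  clique <- snap(c("a", "b", "c", "d"),
                 ~from, ~to, ~weight, ~direction,
                 "a", "b", 1, 0, "a", "c", 1, 0, "a", "d", 1, 0,
                 "b", "c", 1, 0, "b", "d", 1, 0, "c", "d", 1, 0)
  xy1 <- force_layout(clique, seed = 4)
  xy2 <- force_layout(clique, seed = 4)
  expect_identical(xy1, xy2)
  expect_true(all(abs(c(xy1$x, xy1$y)) <= 0.5 + 1e-9))

  # K4 cannot be equilateral in the plane; its energy minimum is a square:
  # four equal sides and two equal (longer) diagonals
  d <- sort(as.numeric(stats::dist(cbind(xy1$x, xy1$y))))
  expect_lt((d[4] - d[1]) / mean(d[1:4]), 0.1)
  expect_lt(abs(d[6] - d[5]) / d[5], 0.1)

  # the triangle's minimum is equilateral: all distances equal within 10%
  tri <- snap(c("a", "b", "c"),
              ~from, ~to, ~weight, ~direction,
              "a", "b", 1, 0, "a", "c", 1, 0, "b", "c", 1, 0)
  dt <- as.numeric(stats::dist(as.matrix(force_layout(tri,
                                                      seed = 4)[, c("x",
                                                                    "y")])))
  expect_lt((max(dt) - min(dt)) / mean(dt), 0.1)

  single <- network_snapshot("solo", tibble::tibble(
    from = character(), to = character(), weight = numeric()))
  expect_equal(force_layout(single), tibble::tibble(node = "solo",
                                                    x = 0, y = 0))
})

test_that("layered layout orders a chain and reports cycle feedback", {
  # a -> b -> c (direction < 0 orients from -> to)
  chain <- snap(c("a", "b", "c"),
                ~from, ~to, ~weight, ~direction,
                "a", "b", 1, -1,
                "b", "c", 1, -1)
  ll <- layered_layout(chain)
  expect_equal(ll$layers$layer[match(c("a", "b", "c"), ll$layers$node)],
               c(0L, 1L, 2L))
  expect_equal(nrow(ll$feedback), 0)

  # 3-cycle: exactly one feedback edge, remaining arcs point downward
  cyc <- snap(c("a", "b", "c"),
              ~from, ~to, ~weight, ~direction,
              "a", "b", 1, -1,    # a -> b
              "b", "c", 1, -1,    # b -> c
              "a", "c", 1,  1)    # c -> a
  llc <- layered_layout(cyc)
  expect_equal(nrow(llc$feedback), 1)

  # random DAGs: every retained edge points to a strictly deeper layer
  withr::with_seed(50, {
    for (rep in 1:5) {
      s <- random_digraph_snapshot(5)
      ll <- layered_layout(s)
      lay <- stats::setNames(ll$layers$layer, ll$layers$node)
      ed <- s$edges[abs(s$edges$direction) > 1e-6, , drop = FALSE]
      src <- ifelse(ed$direction > 0, ed$to, ed$from)
      dst <- ifelse(ed$direction > 0, ed$from, ed$to)
      kept <- !paste(src, dst) %in% paste(ll$feedback$from, ll$feedback$to)
      expect_true(all(lay[src[kept]] < lay[dst[kept]]))
    }
  })
})

test_that("aggregation consistency links full-window GMC to dynamic GMCs", {
  set <- const_coherency_set(c("a", "b", "c"), rhat_value = 0.1 + 0.25i,
                             fs = 100, duration = 2)
  dyn <- build_dynamic_network(set, w = 0.5)
  gmcs <- vapply(dyn$snapshots, global_microscale_connectivity, numeric(1))
  n_bins <- vapply(1:4, function(k)
    sum(set$time >= dyn$windows$t_start[k] &
          set$time <= dyn$windows$t_end[k]), numeric(1))
  full_gmc <- global_microscale_connectivity(build_snapshot(set))
  expect_equal(full_gmc, sum(gmcs * n_bins) / sum(n_bins), tolerance = 1e-9)
})
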