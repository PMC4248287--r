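test_that("topological control preserves the degree sequence with unit weights", {
  for (seed in 1:5) {
    g <- rand_net(30, 0.15, seed)
    ctrl <- topological_control(g, seed = seed + 100)
    expect_equal(node_degree(ctrl), node_degree(g))
    expect_true(all(igraph::E(ctrl)$weight == 1))
    expect_false(igraph::any_loop(ctrl))
    expect_false(igraph::any_multiple(ctrl))
  }
})

test_that("the complete graph is its own unique degree-preserving control", {
  g <- complete_net(5)
  ctrl <- topological_control(g, seed = 7)
  expect_equal(igraph::ecount(ctrl), igraph::ecount(g))
  expect_true(all(igraph::degree(ctrl) == 4))
  # every pair still linked
  expect_equal(sort(apply(igraph::ends(ctrl, igraph::E(ctrl)), 1,
                          function(e) paste(sort(e), collapse = "-"))),
               sort(apply(igraph::ends(g, igraph::E(g)), 1,
                          function(e) paste(sort(e), collapse = "-"))))
})

test_that("rewiring a 4-path samples both realizations of its degree sequence", {
  g <- weighted_network(c("a", "b", "c"), c("b", "c", "d"))
  # simple graphs with degrees (1,2,2,1) on these labels: the original path
  # a-b-c-d and the relabelled path a-c-b-d; count which one each seed lands on
  seen <- character(0)
  for (seed in 1:200) {
    ctrl <- topological_control(g, seed = seed)
    key <- paste(sort(apply(igraph::ends(ctrl, igraph::E(ctrl)), 1,
                            function(e) paste(sort(e), collapse = "-"))),
                 collapse = "|")
    expect_equal(sort(unname(igraph::degree(ctrl)[c("a", "b", "c", "d")])),
                 c(1, 1, 2, 2))
    seen <- c(seen, key)
  }
  tab <- table(seen)
  expect_equal(length(tab), 2)            # both realizations occur
  expect_true(all(tab / 200 > 0.2))       # neither is vanishingly rare
})

test_that("weighted control preserves topology, strengths and total weight", {
  for (seed in 1:10) {
    g <- rand_net(25, 0.2, seed)
    ctrl <- weighted_control(g, seed = seed + 100, tol = 1e-3)
    expect_identical(igraph::as_edgelist(ctrl), igraph::as_edgelist(g))
    s0 <- node_strength(g)
    s1 <- node_strength(ctrl)
    expect_true(all(abs(s1 - s0) / pmax(s0, 1e-12) < 1e-3))
    expect_lt(abs(sum(igraph::E(ctrl)$weight) - sum(igraph::E(g)$weight)) /
                sum(igraph::E(g)$weight), 1e-3)
  }
})

test_that("equal weights are a fixed point of the weighted control", {
  g <- er_weighted(12, 0.5, weight_law("constant", value = 2), seed = 3)
  ctrl <- weighted_control(g, seed = 9)
  expect_equal(igraph::E(ctrl)$weight, igraph::E(g)$weight)
})

test_that("on a triangle, converged weights are pinned by the strengths", {
  # three strengths determine three weights uniquely:
  # w_ab = (s_a + s_b - s_c)/2 etc., so the control must return the original
  # weights up to the tolerance the strengths are held to
  g <- weighted_network(c("a", "b", "c"), c("b", "c", "a"), c(1, 2, 3))
  ctrl <- weighted_control(g, seed = 5, tol = 1e-6)
  w0 <- igraph::E(g)$weight
  w1 <- igraph::E(ctrl)$weight
  expect_equal(w1, w0, tolerance = 1e-4)
})

test_that("mixed control preserves degrees and reduces to rewiring at unit weights", {
  for (seed in 1:5) {
    g <- rand_net(25, 0.2, seed)
    ctrl <- mixed_control(g, seed = seed + 50)
    expect_equal(node_degree(ctrl), node_degree(g))
    s0 <- node_strength(g)
    expect_true(all(abs(node_strength(ctrl) - s0) / pmax(s0, 1e-12) < 1e-3))
  }
  gu <- er_weighted(20, 0.3, weight_law("constant", value = 1), seed = 2)
  ctrl <- mixed_control(gu, seed = 11)
  expect_true(all(igraph::E(ctrl)$weight == 1))
})

test_that("directed shuffle permutes out-weights per node, preserving out-strength", {
  hub <- igraph::graph_from_data_frame(
    data.frame(from = "h", to = c("x", "y", "z"), weight = c(1, 2, 3)),
    directed = TRUE)
  counts <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("1", "2", "3")))
  for (seed in 1:300) {
    sh <- directed_weight_shuffle(hub, "out", seed = seed)
    ends <- igraph::ends(sh, igraph::E(sh))
    for (k in seq_len(3)) {
      counts[ends[k, 2], as.character(igraph::E(sh)$weight[k])] <-
        counts[ends[k, 2], as.character(igraph::E(sh)$weight[k])] + 1
    }
    expect_equal(sum(igraph::strength(sh, mode = "out",
                                      weights = igraph::E(sh)$weight)["h"]), 6)
  }
  # each leaf receives each weight about a third of the time
  expect_true(all(counts / 300 > 0.2 & counts / 300 < 0.47))
})

test_that("directed shuffle leaves singleton out-sets and strengths untouched", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "b"), to = c("b", "c", "d"),
               weight = c(5, 1, 2)), directed = TRUE)
  sh <- directed_weight_shuffle(g, "out", seed = 1)
  expect_equal(igraph::E(sh)$weight[1], 5)   # a's single outgoing link
  outs <- igraph::strength(g, mode = "out", weights = igraph::E(g)$weight)
  expect_equal(igraph::strength(sh, mode = "out",
                                weights = igraph::E(sh)$weight), outs)
  expect_error(directed_weight_shuffle(toy_chain(), "out", seed = 1),
               "directed")
})

test_that("ensembles are seed-deterministic with one row per control", {
  g <- rand_net(20, 0.25, 4)
  thr <- threshold_grid(g, "degree")
  e1 <- build_ensemble(g, "weighted", thr, "degree", n_rand = 8, seed = 99)
  e2 <- build_ensemble(g, "weighted", thr, "degree", n_rand = 8, seed = 99)
  expect_identical(e1$c_samples, e2$c_samples)
  expect_equal(dim(e1$c_samples), c(8, length(thr)))
  expect_true(all(e1$c_samples >= 0))
  # thresholds above the maximum richness give empty clubs, C_rand = 0
  e3 <- build_ensemble(g, "weighted", max(node_degree(g)) + 1, "degree",
                       n_rand = 3, seed = 1)
  expect_true(all(e3$c_samples == 0))
})

test_that("topological ensemble means agree with an independently coded swap loop", {
  g <- rand_net(16, 0.25, 8)
  thr <- stats::median(node_degree(g))
  ens <- build_ensemble(g, "topological", thr, "degree",
                        n_rand = 300, seed = 5)
  pkg_mean <- mean(ens$c_samples)
  withr::with_seed(17, {
    ind <- replicate(300, {
      ed <- oracle_rewire(g, 10 * igraph::ecount(g))
      oracle_c_at(ed, thr)
    })
  })
  se <- sqrt(stats::var(ind) / 300 + stats::var(as.vector(ens$c_samples)) / 300)
  expect_lt(abs(pkg_mean - mean(ind)), 4 * se)
})

test_that("club sizes under sequence-preserving controls match the real network", {
  g <- rand_net(30, 0.2, 12)
  thr <- threshold_grid(g, "degree")
  realN <- vapply(thr, function(t) sum(node_degree(g) > t), numeric(1))
  for (kind in c("topological", "weighted", "mixed")) {
    ctrl <- switch(kind,
                   topological = topological_control(g, seed = 3),
                   weighted = weighted_control(g, seed = 3),
                   mixed = mixed_control(g, seed = 3))
    ctrlN <- vapply(thr, function(t) sum(node_degree(ctrl) > t), numeric(1))
    expect_equal(ctrlN, realN)
  }
})
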