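test_that("modularity matches hand-computed mixing matrices", {
  net <- barbell_net()
  one <- partition(stats::setNames(rep("all", net$n), net$nodes))
  expect_equal(modularity_q(net, one), 0)

  split <- partition(stats::setNames(
    c("L", "L", "L", "R", "R", "R"), c("a", "b", "c", "x", "y", "z")))
  expect_equal(modularity_q(net, split), 5 / 14)

  k <- load_fixture("karate")
  expect_equal(modularity_q(k$network, k$truth), 0.3715, tolerance = 1e-3)
})

test_that("mixing-matrix modularity equals the degree-based formulation", {
  for (seed in 1:100) {
    net <- random_net(sample(5:20, 1L), stats::runif(1, 0.2, 0.7), seed)
    p <- random_partition(net$nodes, sample(2:4, 1L), seed + 1000)
    expect_equal(modularity_q(net, p), modularity_degree_form(net, p),
                 tolerance = 1e-12)
  }
})

test_that("modularity agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    net <- random_net(12, 0.4, seed)
    p <- random_partition(net$nodes, 3L, seed + 1)
    g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    memb <- as.integer(factor(p$assignment[igraph::V(g)$name]))
    expect_equal(modularity_q(net, p), igraph::modularity(g, memb),
                 tolerance = 1e-12)
  }
})

test_that("label matching follows the iterative plurality procedure", {
  truth <- partition(c(`1` = "L1", `2` = "L1", `3` = "L1",
                       `4` = "L2", `5` = "L2"))
  pred <- partition(c(`1` = "p1", `2` = "p1",
                      `3` = "p2", `4` = "p2", `5` = "p2"))
  m <- match_labels(truth, pred)
  expect_equal(unname(m$matching[c("p1", "p2")]), c("L1", "L2"))
  expect_equal(accuracy(truth, pred), 0.8)
  expect_setequal(misclassified_nodes(truth, pred), "3")

  # conflicting claims: the larger claim wins, the loser is removed
  truth2 <- partition(c(a = "L1", b = "L1", c = "L1", d = "L1", e = "L1"))
  pred2 <- partition(c(a = "c1", b = "c1", c = "c1", d = "c2", e = "c2"))
  m2 <- match_labels(truth2, pred2)
  expect_equal(unname(m2$matching[["c1"]]), "L1")
  expect_true(is.na(m2$matching[["c2"]]))
  expect_equal(accuracy(truth2, pred2), 3 / 5)

  expect_equal(accuracy(truth, truth), 1)
})

test_that("losers fall back to their next-most-frequent label", {
  truth <- partition(c(a = "L1", b = "L1", c = "L1", d = "L1",
                       e = "L2", f = "L2", g = "L2"))
  # both claim L1 with two members each; the larger community keeps it and
  # the loser falls back to its remaining label
  pred <- partition(c(a = "c1", b = "c1", e = "c1",
                      c = "c2", d = "c2", f = "c2", g = "c2"))
  m <- match_labels(truth, pred)
  expect_equal(unname(m$matching[["c2"]]), "L1")
  expect_equal(unname(m$matching[["c1"]]), "L2")
  expect_setequal(misclassified_nodes(truth, pred), c("a", "b", "f", "g"))
})

test_that("NMI behaves on identical, independent and degenerate labelings", {
  t1 <- partition(c(a = "x", b = "x", c = "y", d = "y"))
  expect_equal(nmi(t1, t1), 1)

  ind <- partition(c(a = "p", b = "q", c = "p", d = "q"))
  expect_equal(nmi(t1, ind), 0)

  single <- partition(c(a = "s", b = "s", c = "s", d = "s"))
  expect_equal(nmi(t1, single), 0)
  expect_equal(nmi(single, single), 1)
})

test_that("accuracy and NMI are invariant to community relabeling", {
  for (seed in 1:10) {
    net <- random_net(12, 0.4, seed)
    truth <- random_partition(net$nodes, 3L, seed)
    pred <- random_partition(net$nodes, 3L, seed + 50)
    truth2 <- relabel_partition(truth, seed + 1)
    pred2 <- relabel_partition(pred, seed + 2)
    expect_equal(accuracy(truth, pred), accuracy(truth2, pred2))
    expect_equal(nmi(truth, pred), nmi(truth2, pred2))
    expect_equal(nmi(truth, pred), nmi(pred, truth))
    expect_gte(nmi(truth, pred), 0)
    expect_lte(nmi(truth, pred), 1)
    expect_gte(accuracy(truth, pred), 0)
    expect_lte(accuracy(truth, pred), 1)
  }
})

test_that("modularity stays within its theoretical range", {
  for (seed in 1:10) {
    net <- random_net(10, 0.5, seed)
    p <- random_partition(net$nodes, sample(2:5, 1L), seed + 10)
    q <- modularity_q(net, p)
    expect_gte(q, -1)
    expect_lte(q, 1)
  }
})

test_that("evaluate_partition bundles the three metrics", {
  k <- load_fixture("karate")
  ev <- evaluate_partition(k$network, k$truth, k$truth)
  expect_equal(ev$A, 1)
  expect_equal(ev$NMI, 1)
  expect_equal(round(ev$Q, 3), 0.371)
  expect_length(ev$misclassified, 0L)
})
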