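test_that("node scores are degree ratios against the strongest neighbor", {
  pth <- path_net()
  expect_equal(node_score(pth, "b"), 2)
  expect_equal(node_score(pth, "a"), 0.5)

  star <- network(cbind("hub", c("l1", "l2", "l3")))
  expect_equal(node_score(star, "hub"), 3)
  expect_equal(node_score(star, "l1"), 1 / 3)

  reg <- complete_net(c("a", "b", "c", "d"))
  expect_true(all(vapply(reg$nodes, function(v) node_score(reg, v),
                         numeric(1L)) == 1))

  iso <- network(cbind("u", "v"), nodes = c("u", "v", "z"))
  expect_warning(s <- node_score(iso, "z"), "isolated")
  expect_equal(s, 0)
})

test_that("candidate extraction keeps the top fraction of score values", {
  pth <- path_net()
  expect_setequal(extract_candidates(pth, 1), pth$nodes)
  # scores 0.5, 2, 0.5: two distinct values, top 34% keeps only the maximum
  expect_equal(extract_candidates(pth, 0.34), "b")
  # regular graph: single score value, everyone stays
  reg <- complete_net(c("a", "b", "c", "d"))
  expect_setequal(extract_candidates(reg, 0.5), reg$nodes)
})

test_that("local similarity counts shared neighbors plus adjacency", {
  tri <- triangle_net()
  expect_equal(local_similarity(tri, "a", "b"), 2)
  pth <- path_net()
  expect_equal(local_similarity(pth, "a", "c"), 1)
  disc <- network(rbind(c("a", "b"), c("x", "y")))
  expect_equal(local_similarity(disc, "a", "x"), 0)
  expect_error(local_similarity(tri, "a", "a"), "distinct")
})

test_that("msn waves cluster candidates without crossing sparse cuts", {
  net <- barbell_net()
  cs <- partition_into_clusters(net, net$nodes)
  expect_length(cs$clusters, 2L)
  expect_setequal(cs$clusters[[1L]], c("a", "b", "c"))
  expect_setequal(cs$clusters[[2L]], c("x", "y", "z"))

  single <- partition_into_clusters(net, "a")
  expect_equal(single$clusters, list("a"))

  comp <- complete_net(c("a", "b", "c", "d"))
  expect_length(partition_into_clusters(comp, comp$nodes)$clusters, 1L)
})

test_that("representatives are the maximal-degree members, ties by score", {
  net <- network(rbind(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c")))
  cs <- structure(list(clusters = list(c("a", "b")), representatives = NULL),
                  class = "sscd_clusters")
  expect_equal(select_representatives(net, cs)$representatives, "a")

  # degree tie between b and c: score decides (equal here), then smaller id
  cs2 <- structure(list(clusters = list(c("b", "c")), representatives = NULL),
                   class = "sscd_clusters")
  expect_equal(select_representatives(net, cs2)$representatives, "b")
})

test_that("the oracle answers from ground truth and counts queries", {
  truth <- partition(c(a = "1", b = "1", c = "2"))
  o <- make_oracle(truth)
  expect_true(oracle_query(o, "a", "b"))
  expect_false(oracle_query(o, "a", "c"))
  expect_equal(o$queries_used, 2L)
  expect_error(oracle_query(o, "a", "zz"), "no truth")
})

test_that("karate representative acquisition selects the two faction hubs", {
  k <- load_fixture("karate")
  res <- acquire_constraints(k$network, make_oracle(k$truth),
                             active_config(phases = character()))
  expect_equal(res$selected, c("1", "34"))
  expect_equal(nrow(res$log), 1L)
  expect_equal(res$log$response, "CL")
  expect_equal(nrow(res$store$cannot_link), 1L)
  expect_equal(nrow(res$store$must_link), 0L)
})

test_that("acquisition respects query and node budgets and logs every query", {
  g <- load_fixture("planted4", seed = 2)
  o <- make_oracle(g$truth)
  res <- acquire_constraints(g$network, o, active_config(query_budget = 5))
  expect_equal(nrow(res$log), 5L)
  expect_equal(o$queries_used, 5L)

  o2 <- make_oracle(g$truth)
  res2 <- acquire_constraints(g$network, o2, active_config(node_budget = 4))
  expect_lte(length(res2$selected), 4L)

  o3 <- make_oracle(g$truth)
  res3 <- acquire_constraints(g$network, o3, active_config(query_budget = 0))
  expect_equal(nrow(res3$log), 0L)
  expect_equal(nrow(res3$store$must_link) + nrow(res3$store$cannot_link), 0L)
})

test_that("acquired stores are consistent and phases extend the coverage", {
  for (seed in 1:5) {
    g <- load_fixture("planted4", seed = seed)
    o <- make_oracle(g$truth)
    res <- acquire_constraints(g$network, o, active_config())
    expect_true(check_consistency(close_constraints(res$store))$ok)
    expect_equal(nrow(res$log), o$queries_used)
    # representatives cover every planted block
    reps <- res$clusters$representatives
    expect_equal(length(unique(g$truth$assignment[reps])), g$truth$k)
  }
})

test_that("representative dedup keeps one hub per ground-truth community", {
  g <- load_fixture("planted4", seed = 7)
  res <- acquire_constraints(g$network, make_oracle(g$truth),
                             active_config(phases = character(),
                                           dedup_representatives = TRUE))
  reps <- res$clusters$representatives
  expect_equal(anyDuplicated(g$truth$assignment[reps]), 0L)
  # with deduped representatives every phase-0 answer is a cannot-link
  expect_true(all(res$log$response == "CL"))
})
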