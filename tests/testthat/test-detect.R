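test_that("cannot-link endpoints seed the skeleton, must-links merge seeds", {
  k <- load_fixture("karate")
  st <- close_constraints(constraint_store(cannot_link = rbind(c("1", "34"))))
  state <- build_skeleton(k$network, st)
  expect_equal(state$communities, list("1", "34"))
  expect_length(state$unclassified, 32L)

  net <- network(rbind(c("1", "2"), c("1", "4"), c("2", "3"), c("3", "4")))
  st2 <- close_constraints(constraint_store(
    must_link = rbind(c("1", "2")),
    cannot_link = rbind(c("1", "4"), c("2", "3"))))
  state2 <- build_skeleton(net, st2)
  expect_equal(lapply(state2$communities, sort),
               list(c("1", "2"), "4", "3"))

  expect_error(build_skeleton(net, close_constraints(
    constraint_store(must_link = rbind(c("1", "2"))))), "no seeds")
})

test_that("must-link absorption pulls whole groups into seeded communities", {
  ids <- as.character(1:6)
  net <- network(cbind(ids[-6], ids[-1]))
  st <- close_constraints(constraint_store(
    must_link = rbind(c("4", "5"), c("5", "6")),
    cannot_link = rbind(c("1", "4"))))
  state <- absorb_must_link(build_skeleton(net, st))
  expect_equal(lapply(state$communities, sort), list("1", c("4", "5", "6")))
  expect_setequal(state$unclassified, c("2", "3"))

  # no must-links touching the unclassified set: fixpoint immediately
  st2 <- close_constraints(constraint_store(cannot_link = rbind(c("1", "6"))))
  state2 <- build_skeleton(net, st2)
  expect_equal(absorb_must_link(state2), state2)
})

test_that("greedy expansion is deterministic and obeys the similarity order", {
  net <- network(rbind(c("a", "b"), c("a", "x"), c("x", "y")))
  S <- matrix(0, 4, 4, dimnames = list(net$nodes, net$nodes))
  S["a", "b"] <- S["b", "a"] <- 7
  S["x", "y"] <- S["y", "x"] <- 5
  st <- close_constraints(constraint_store(cannot_link = rbind(c("a", "x"))))
  state <- absorb_must_link(build_skeleton(net, st))
  p <- expand_greedy(state, S, net)
  expect_equal(unname(p$assignment[c("a", "b")]), c("C1", "C1"))
  expect_equal(unname(p$assignment[c("x", "y")]), c("C2", "C2"))
})

test_that("zero-similarity nodes attach through their classified neighbors", {
  ids <- c("a", "b", "c", "d", "e")
  net <- network(cbind(ids[-5], ids[-1]))
  S <- matrix(0, 5, 5, dimnames = list(net$nodes, net$nodes))
  st <- constraint_store(cannot_link = rbind(c("a", "e")))
  p <- detect_communities(net, st, S)
  expect_equal(sort(unique(unname(p$assignment))), c("C1", "C2"))
  expect_false(p$assignment[["a"]] == p$assignment[["e"]])
  # chain attachment keeps each node with a classified neighbor; the
  # tie at d (neighbors c and e have equal degree) breaks by node id
  expect_equal(p$assignment[["b"]], p$assignment[["a"]])
  expect_equal(p$assignment[["c"]], p$assignment[["a"]])
  expect_equal(p$assignment[["d"]], p$assignment[["a"]])
})

test_that("detection output satisfies every closed constraint", {
  for (seed in 1:6) {
    g <- generate_planted_partition(c(8, 8, 8), 0.6, 0.05, seed = seed,
                                    require_connected = TRUE)
    truth <- g$truth
    nodes <- names(truth$assignment)
    st <- withr::with_seed(seed, {
      cl <- NULL; ml <- NULL
      for (i in 1:6) {
        pr <- sample(nodes, 2L)
        if (truth$assignment[pr[1L]] == truth$assignment[pr[2L]]) {
          ml <- rbind(ml, pr)
        } else {
          cl <- rbind(cl, pr)
        }
      }
      constraint_store(ml, cl)
    })
    if (nrow(close_constraints(st)$cannot_link) == 0L) next
    S <- compute_similarity(g$network, seed = seed)
    p <- detect_communities(g$network, st, S)
    closed <- close_constraints(st)
    a <- p$assignment
    expect_true(all(a[closed$must_link[, 1L]] == a[closed$must_link[, 2L]]))
    expect_true(all(a[closed$cannot_link[, 1L]] != a[closed$cannot_link[, 2L]]))
    # valid partition: disjoint, exhaustive, no empty community
    expect_setequal(names(a), g$network$nodes)
    expect_true(all(vapply(p$communities, length, integer(1L)) > 0L))
    # deterministic given (network, constraints, similarity)
    expect_identical(detect_communities(g$network, st, S), p)
  }
})

test_that("two constrained nodes on one edge split into singletons", {
  net <- network(cbind("u", "v"))
  S <- compute_similarity(net, seed = 1)
  p <- detect_communities(net, constraint_store(
    cannot_link = rbind(c("u", "v"))), S)
  expect_equal(p$k, 2L)
  expect_equal(unname(sort(vapply(p$communities, length, integer(1L)))),
               c(1L, 1L))
})

test_that("inconsistent or seedless constraint stores are rejected", {
  net <- triangle_net()
  S <- compute_similarity(net, seed = 1)
  expect_error(detect_communities(net, constraint_store(
    must_link = rbind(c("a", "b")), cannot_link = rbind(c("a", "b"))), S),
    "inconsistent")
  expect_error(detect_communities(net, constraint_store(
    must_link = rbind(c("a", "b"))), S), "no seeds")
})
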