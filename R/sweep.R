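#' End-to-end active detection
#'
#' Convenience wrapper: acquire constraints actively against an oracle built
#' from the ground truth, compute the random-walk similarity, and run the
#' constrained detection.
#'
#' @param net an [network()] object.
#' @param truth ground-truth [partition()] backing the oracle.
#' @param cfg an [active_config()].
#' @param l,walks_per_node random-walk parameters (see
#'   [compute_similarity()]).
#' @param seed optional seed for the random walks.
#' @param S optional precomputed similarity matrix (overrides
#'   `l`/`walks_per_node`/`seed`).
#' @return A list with `partition`, `store`, `selected`, `log`,
#'   `queries_used`.
#' @export
active_detect <- function(net, truth, cfg = active_config(), l = net$n,
                          walks_per_node = 1L, seed = NULL, S = NULL) {
  oracle <- make_oracle(truth)
  acq <- acquire_constraints(net, oracle, cfg)
  if (is.null(S)) {
    S <- compute_similarity(net, l = l, walks_per_node = walks_per_node,
                            seed = seed)
  }
  p <- detect_from_store(net, acq$store, S)
  list(partition = p, store = acq$store, selected = acq$selected,
       log = acq$log, queries_used = oracle$queries_used)
}

# detect, falling back to a single all-in-one community when the store has
# no cannot-link seed (possible for random acquisition strategies whose
# selected nodes all share a community)
detect_from_store <- function(net, store, S) {
  closed <- close_constraints(store)
  if (nrow(closed$cannot_link) == 0L) {
    return(partition(stats::setNames(rep("C1", net$n), net$nodes)))
  }
  detect_communities(net, store, S)
}

random_constraints <- function(net, oracle, n_nodes, stratified) {
  truth <- oracle$truth
  if (stratified) {
    # one node per ground-truth community first, remainder fully random
    picks <- vapply(truth$communities, function(cc) {
      cc <- intersect(cc, net$nodes)
      cc[sample.int(length(cc), 1L)]
    }, character(1L))
    picks <- unname(picks)
    rest <- setdiff(net$nodes, picks)
    extra <- n_nodes - length(picks)
    if (extra > 0L) picks <- c(picks, sample(rest, extra))
  } else {
    picks <- sample(net$nodes, n_nodes)
  }
  ml <- matrix(character(), ncol = 2L)
  cl <- matrix(character(), ncol = 2L)
  if (length(picks) > 1L) {
    pairs <- utils::combn(picks, 2L)
    for (r in seq_len(ncol(pairs))) {
      if (oracle_query(oracle, pairs[1L, r], pairs[2L, r])) {
        ml <- rbind(ml, pairs[, r])
      } else {
        cl <- rbind(cl, pairs[, r])
      }
    }
  }
  constraint_store(must_link = ml, cannot_link = cl)
}

#' Compare active against random constraint acquisition
#'
#' For each node budget and strategy, constraints are generated (actively,
#' or by querying the oracle on all pairs of randomly selected nodes), the
#' constrained detection is run, and modularity, accuracy and NMI are
#' recorded. Random strategies are repeated and reported per repeat;
#' `random_stratified` first covers every ground-truth community with one
#' node, mirroring the covering random baseline, whereas `random_uniform`
#' samples nodes completely at random. The same random-walk similarity
#' matrix backs every run on the network.
#'
#' @param net an [network()] object.
#' @param truth ground-truth [partition()].
#' @param budgets increasing integer vector of selected-node counts.
#' @param strategies subset of `c("active", "random_uniform",
#'   "random_stratified")`.
#' @param repeats repeats per random strategy (default 10; active is
#'   deterministic given the similarity matrix and runs once).
#' @param score_fraction candidate fraction for the active strategy.
#' @param dedup_representatives see [active_config()].
#' @param l,walks_per_node random-walk similarity parameters (see
#'   [compute_similarity()]).
#' @param seed seed for the similarity matrix and the random selections.
#' @return A long-format data frame with columns `budget`, `strategy`,
#'   `repeat_id`, `nodes_used`, `queries`, `Q`, `A`, `NMI`.
#' @export
run_sweep <- function(net, truth, budgets,
                      strategies = c("active", "random_uniform",
                                     "random_stratified"),
                      repeats = 10L, score_fraction = 0.5,
                      dedup_representatives = FALSE, l = net$n,
                      walks_per_node = 1L, seed = NULL) {
  stopifnot(all(diff(budgets) >= 0), repeats >= 1L,
            all(strategies %in% c("active", "random_uniform",
                                  "random_stratified")))
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  if (any(budgets > net$n)) {
    warning("budget(s) larger than the network clipped to n = ", net$n,
            call. = FALSE)
    budgets <- pmin(budgets, net$n)
  }
  S <- compute_similarity(net, l = l, walks_per_node = walks_per_node)
  rows <- list()
  add_row <- function(budget, strategy, repeat_id, store, oracle, selected) {
    p <- detect_from_store(net, store, S)
    rows[[length(rows) + 1L]] <<- data.frame(
      budget = budget, strategy = strategy, repeat_id = repeat_id,
      nodes_used = length(selected), queries = oracle$queries_used,
      Q = modularity_q(net, p), A = accuracy(truth, p),
      NMI = nmi(truth, p))
  }
  for (budget in budgets) {
    for (strategy in strategies) {
      if (strategy == "active") {
        oracle <- make_oracle(truth)
        acq <- acquire_constraints(
          net, oracle,
          active_config(score_fraction = score_fraction,
                        node_budget = budget,
                        dedup_representatives = dedup_representatives))
        add_row(budget, strategy, 1L, acq$store, oracle, acq$selected)
      } else {
        for (r in seq_len(repeats)) {
          oracle <- make_oracle(truth)
          store <- random_constraints(net, oracle, budget,
                                      strategy == "random_stratified")
          add_row(budget, strategy, r, store, oracle,
                  unique(as.vector(rbind(store$must_link,
                                         store$cannot_link))))
        }
      }
    }
  }
  do.call(rbind, rows)
}
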