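#' Build the community skeleton from constraints
#'
#' Every node appearing in a cannot-link pair seeds its own singleton
#' community; communities whose seeds are related by (closed) must-links are
#' merged. All remaining nodes start unclassified. The skeleton is built
#' purely from constraints — cannot-link endpoints are the community
#' initiators.
#'
#' @param net an [network()] object.
#' @param store a **closed, consistent** [constraint_store()].
#' @return A detection state: list with `communities` (list of character
#'   vectors in creation order), `unclassified` (character vector), `store`,
#'   and `groups` (node -> must-link group id for constrained nodes).
#' @export
build_skeleton <- function(net, store) {
  stopifnot(inherits(net, "sscd_network"), inherits(store, "sscd_constraints"))
  if (!isTRUE(store$closed)) stop("store must be closed (see close_constraints)")
  if (nrow(store$cannot_link) == 0L) {
    stop("no cannot-link constraints: the skeleton has no seeds")
  }
  missing <- setdiff(unique(c(as.vector(store$must_link),
                              as.vector(store$cannot_link))), net$nodes)
  if (length(missing)) {
    stop("constraint node(s) not in network: ",
         paste(missing, collapse = ", "))
  }
  groups <- ml_groups(store)
  # seeds in first-appearance order over the cannot-link rows
  seeds <- unique(as.vector(t(store$cannot_link)))
  communities <- list()
  comm_of_group <- integer()     # ml group id -> community index
  for (v in seeds) {
    g <- groups[[v]]
    at <- comm_of_group[as.character(g)]
    if (is.na(at) || length(at) == 0L) {
      communities[[length(communities) + 1L]] <- v
      comm_of_group[as.character(g)] <- length(communities)
    } else {
      communities[[at]] <- c(communities[[at]], v)
    }
  }
  classified <- unlist(communities, use.names = FALSE)
  list(communities = communities,
       unclassified = setdiff(net$nodes, classified),
       store = store,
       groups = groups)
}

#' Absorb must-linked nodes into the skeleton
#'
#' Unclassified nodes sharing a (closed) must-link group with any classified
#' node join that node's community, repeatedly until a fixpoint. Because the
#' store is closed, one pass over the groups reaches the fixpoint.
#'
#' @param state a detection state from [build_skeleton()].
#' @return The updated state.
#' @export
absorb_must_link <- function(state) {
  groups <- state$groups
  for (i in seq_along(state$communities)) {
    members <- state$communities[[i]]
    gids <- unique(groups[intersect(members, names(groups))])
    if (length(gids) == 0L) next
    buddies <- names(groups)[groups %in% gids]
    pull <- intersect(state$unclassified, buddies)
    if (length(pull)) {
      state$communities[[i]] <- c(members, pull)
      state$unclassified <- setdiff(state$unclassified, pull)
    }
  }
  state
}

#' Greedily expand the skeleton to a full partition
#'
#' While unclassified nodes remain, the (community, node) pair with the
#' globally largest community-to-node similarity (the maximum over members)
#' is selected; the node joins that community, followed by any unclassified
#' members of its must-link group. Ties break to the smallest node id, then
#' the lowest community creation index. Nodes with zero similarity to every
#' community are deferred until all positive-similarity nodes are placed,
#' then attached to the community holding their highest-degree classified
#' neighbor (isolated leftovers go to the largest community, with a
#' warning).
#'
#' @param state a detection state (after [absorb_must_link()]).
#' @param S an `sscd_similarity` matrix.
#' @param net the [network()] the state was built from.
#' @return An [partition()] with communities labelled `C1`, `C2`, ... in
#'   creation order.
#' @export
expand_greedy <- function(state, S, net) {
  communities <- state$communities
  k <- length(communities)
  groups <- state$groups
  # best[i, v]: similarity between community i and node v (max over members)
  best <- matrix(-Inf, k, net$n, dimnames = list(NULL, net$nodes))
  for (i in seq_len(k)) {
    best[i, ] <- if (length(communities[[i]]) == 1L) {
      S[communities[[i]], ]
    } else {
      apply(S[communities[[i]], , drop = FALSE], 2L, max)
    }
  }
  U <- sort(state$unclassified, method = "radix")

  insert <- function(i, v) {
    communities[[i]] <<- c(communities[[i]], v)
    U <<- setdiff(U, v)
    best[, v] <<- -Inf
    upd <- S[v, ] > best[i, ]
    best[i, upd] <<- S[v, upd]
    # step 6's repeat loop: must-link buddies follow immediately
    g <- groups[v]
    if (!is.na(g)) {
      buddies <- intersect(U, names(groups)[groups == g])
      for (b in buddies) {
        communities[[i]] <<- c(communities[[i]], b)
        U <<- setdiff(U, b)
        best[, b] <<- -Inf
        upd <- S[b, ] > best[i, ]
        best[i, upd] <<- S[b, upd]
      }
    }
  }

  while (length(U)) {
    M <- best[, U, drop = FALSE]
    mx <- max(M)
    if (mx <= 0) break  # only zero-similarity nodes remain; defer
    v <- U[which(apply(M, 2L, max) == mx)][1L]   # U sorted: smallest id wins
    i <- which(best[, v] == mx)[1L]              # lowest creation index
    insert(i, v)
  }

  # deferred zero-similarity nodes
  while (length(U)) {
    placed <- FALSE
    for (v in U) {
      cls <- setdiff(neighbors_of(net, v), U)
      if (length(cls)) {
        nb <- cls[order(-degrees(net, cls), cls)][1L]
        i <- which(vapply(communities, function(cc) nb %in% cc, logical(1L)))[1L]
        insert(i, v)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      v <- U[1L]
      i <- which.max(vapply(communities, length, integer(1L)))
      warning("node '", v, "' has no classified neighbor; ",
              "attached to the largest community", call. = FALSE)
      insert(i, v)
    }
  }

  labels <- paste0("C", seq_len(k))
  partition(stats::setNames(
    rep(labels, vapply(communities, length, integer(1L))),
    unlist(communities, use.names = FALSE)
  ))
}

#' Semi-supervised community detection
#'
#' End-to-end constrained detection: the constraint store is transitively
#' closed and checked for consistency, cannot-link endpoints seed the
#' community skeleton, must-linked nodes are absorbed, and the remaining
#' nodes are assigned greedily by descending community-to-node random-walk
#' similarity. The result satisfies every closed must-link (co-membership)
#' and cannot-link (separation) constraint.
#'
#' @param net an [network()] object.
#' @param store an [constraint_store()]; closure is applied internally, so a
#'   raw store is fine. Must contain at least one cannot-link constraint and
#'   be consistent after closure.
#' @param S an `sscd_similarity` matrix from [compute_similarity()].
#' @return An [partition()] covering all nodes of `net`.
#' @examples
#' k <- load_fixture("karate")
#' S <- compute_similarity(k$network, seed = 1)
#' p <- detect_communities(k$network, constraint_store(
#'   cannot_link = rbind(c("1", "34"))), S)
#' p$k
#' @export
detect_communities <- function(net, store, S) {
  closed <- close_constraints(store)
  chk <- check_consistency(closed)
  if (!chk$ok) {
    stop("inconsistent constraints, e.g. pair (",
         chk$conflicts[1L, 1L], ", ", chk$conflicts[1L, 2L],
         ") is both must-link and cannot-link after closure")
  }
  state <- build_skeleton(net, closed)
  state <- absorb_must_link(state)
  p <- expand_greedy(state, S, net)
  assert_constraints_satisfied(p, closed)
  p
}

# postcondition check: closed ML pairs co-assigned, closed CL pairs split
assert_constraints_satisfied <- function(p, closed) {
  a <- p$assignment
  if (nrow(closed$must_link)) {
    viol <- a[closed$must_link[, 1L]] != a[closed$must_link[, 2L]]
    if (any(viol)) stop("internal error: must-link pair separated")
  }
  if (nrow(closed$cannot_link)) {
    viol <- a[closed$cannot_link[, 1L]] == a[closed$cannot_link[, 2L]]
    if (any(viol)) stop("internal error: cannot-link pair co-assigned")
  }
  invisible(TRUE)
}
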