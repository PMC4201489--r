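#' Degree-based node score
#'
#' `score(v) = d(v) / max_{u in Gamma(v)} d(u)`: a node scores at least 1
#' exactly when its degree is a local maximum. Ranking by this score (rather
#' than by raw degree) lets the hub of a small community surface even when a
#' bigger hub exists elsewhere in the network.
#'
#' @param net an [network()] object.
#' @param v a node id.
#' @return The score (0, with a warning, for an isolated node).
#' @export
node_score <- function(net, v) {
  d <- degrees(net, v)
  if (d == 0L) {
    warning("node '", v, "' is isolated; score 0", call. = FALSE)
    return(0)
  }
  unname(d / max(degrees(net, neighbors_of(net, v))))
}

node_scores <- function(net) {
  d <- degrees(net)
  vapply(net$nodes, function(v) {
    if (d[[v]] == 0L) 0 else d[[v]] / max(d[net$adj[[v]]])
  }, numeric(1L))
}

#' Extract high-score candidate nodes
#'
#' Keeps the nodes whose score is among the top `score_fraction` of the
#' distinct score values occurring in the network: the threshold is the
#' `ceiling(fraction * v)`-th largest of the `v` distinct values, and every
#' node at or above the threshold is included (so in a regular graph, where
#' a single score value occurs, every node is a candidate).
#'
#' @param net an [network()] object.
#' @param score_fraction fraction in `(0, 1]` of the distinct score values
#'   to keep (default 0.5).
#' @return Character vector of candidate node ids.
#' @export
extract_candidates <- function(net, score_fraction = 0.5) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  sc <- node_scores(net)
  vals <- sort(unique(sc), decreasing = TRUE)
  thr <- vals[ceiling(score_fraction * length(vals))]
  net$nodes[sc >= thr]
}

#' Local similarity between two nodes
#'
#' Shared-neighbor count plus an adjacency indicator:
#' `S(u, v) = |Gamma(u) ∩ Gamma(v)| + [u ~ v]`. Purely local and cheap; used
#' to cluster the candidate set quickly before any oracle access.
#'
#' @param net an [network()] object.
#' @param u,v distinct node ids.
#' @return A nonnegative integer.
#' @export
local_similarity <- function(net, u, v) {
  if (u == v) stop("local similarity is defined for distinct nodes")
  length(intersect(net$adj[[u]], net$adj[[v]])) + (v %in% net$adj[[u]])
}

#' Cluster the candidate set by most-similar-neighbor waves
#'
#' Local similarity is computed for all candidate pairs; each candidate's
#' *most similar neighbor* (msn) is the candidate attaining its maximal
#' positive similarity, ties broken toward the larger degree and then the
#' smaller id (a candidate ties to a community hub rather than to a peer, so
#' msn links point up the local degree hierarchy and do not leak across
#' community boundaries through shared low-degree nodes). Every candidate
#' starts as a singleton cluster; the highest-degree unprocessed candidate
#' becomes a pivot, its cluster is merged with the cluster of its msn, and
#' the msn becomes a pivot in turn (a breadth-first wave over msn links)
#' until the wave closes; then the next unprocessed candidate starts a new
#' wave.
#'
#' @param net an [network()] object.
#' @param cand character vector of candidate node ids (non-empty).
#' @return Object of class `sscd_clusters`: list with `clusters` (list of
#'   character vectors) and `representatives` (set by
#'   [select_representatives()]; `NULL` here).
#' @export
partition_into_clusters <- function(net, cand) {
  if (length(cand) == 0L) stop("candidate set is empty")
  cand <- sort(unique(cand), method = "radix")
  nc <- length(cand)
  Sl <- matrix(0, nc, nc, dimnames = list(cand, cand))
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) {
      for (j in seq.int(i + 1L, nc)) {
        Sl[i, j] <- Sl[j, i] <- local_similarity(net, cand[i], cand[j])
      }
    }
  }
  dd <- degrees(net, cand)
  msn <- lapply(stats::setNames(cand, cand), function(v) {
    s <- Sl[v, setdiff(cand, v)]
    if (length(s) == 0L || max(s) <= 0) return(character())
    m <- names(s)[s == max(s)]
    m[order(-dd[m], m, method = "radix")][1L]
  })
  # union-find over candidates
  parent <- stats::setNames(seq_len(nc), cand)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  unite <- function(u, v) {
    ru <- find(match(u, cand)); rv <- find(match(v, cand))
    if (ru != rv) parent[[rv]] <<- ru
  }
  d <- degrees(net, cand)
  sc <- node_scores(net)[cand]
  processed <- stats::setNames(rep(FALSE, nc), cand)
  order_key <- order(-d, cand, method = "radix")
  for (root in cand[order_key]) {
    if (processed[[root]]) next
    queue <- root
    processed[[root]] <- TRUE
    while (length(queue)) {
      pivot <- queue[[1L]]
      queue <- queue[-1L]
      for (u in msn[[pivot]]) {
        unite(pivot, u)
        if (!processed[[u]]) {
          processed[[u]] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1L))
  clusters <- unname(split(cand, roots))
  # deterministic cluster order: by max member degree desc, then first id
  key <- order(-vapply(clusters, function(cc) max(d[cc]), numeric(1L)),
               vapply(clusters, `[[`, character(1L), 1L),
               method = "radix")
  structure(list(clusters = clusters[key], representatives = NULL),
            class = "sscd_clusters")
}

#' Select cluster representatives
#'
#' The representative of each cluster is its maximal-degree member; degree
#' ties break toward the larger score, residual ties toward the smaller id.
#'
#' @param net an [network()] object.
#' @param clusters an `sscd_clusters` object.
#' @return The `sscd_clusters` object with `representatives` filled in
#'   (character vector aligned with `clusters`).
#' @export
select_representatives <- function(net, clusters) {
  sc <- node_scores(net)
  clusters$representatives <- vapply(clusters$clusters, function(cc) {
    d <- degrees(net, cc)
    cc[order(-d, -sc[cc], cc, method = "radix")][1L]
  }, character(1L))
  clusters
}

#' @export
print.sscd_clusters <- function(x, ...) {
  cat("<sscd_clusters> ", length(x$clusters), " clusters over ",
      length(unlist(x$clusters)), " candidates\n", sep = "")
  invisible(x)
}

#' Create a noiseless pairwise oracle
#'
#' The oracle answers whether two nodes share a ground-truth community,
#' without error, and counts its queries.
#'
#' @param truth an [partition()] used as ground truth.
#' @return Object of class `sscd_oracle` (an environment with `truth` and
#'   `queries_used`).
#' @export
make_oracle <- function(truth) {
  stopifnot(inherits(truth, "sscd_partition"))
  o <- new.env(parent = emptyenv())
  o$truth <- truth
  o$queries_used <- 0L
  class(o) <- "sscd_oracle"
  o
}

#' Query the oracle about a node pair
#'
#' @param oracle an [make_oracle()] object.
#' @param u,v distinct node ids covered by the oracle's ground truth.
#' @return `TRUE` for must-link (same community), `FALSE` for cannot-link.
#' @export
oracle_query <- function(oracle, u, v) {
  stopifnot(inherits(oracle, "sscd_oracle"), u != v)
  a <- oracle$truth$assignment
  if (is.na(a[u]) || is.na(a[v])) stop("oracle has no truth for the pair")
  oracle$queries_used <- oracle$queries_used + 1L
  unname(a[u] == a[v])
}

#' Active acquisition configuration
#'
#' @param score_fraction fraction of top score values kept as candidates
#'   (default 0.5).
#' @param query_budget maximum oracle queries (default unlimited).
#' @param node_budget maximum distinct nodes involved in queries (default
#'   unlimited).
#' @param phases which follow-up phases run after the representative-pair
#'   phase: `"ties"` (same-maximal-degree cluster members) and/or
#'   `"boundary"` (cross-cluster boundary members). Empty for a
#'   representatives-only run.
#' @param dedup_representatives drop same-community representatives before
#'   querying (keep the larger degree, then larger score), emulating the
#'   manual pre-selection used on benchmarks where several cluster hubs sit
#'   in one ground-truth community; the ground-truth peeks used for the
#'   dedup are not counted as oracle queries and add no constraints.
#' @return A list of class `sscd_active_config`.
#' @export
active_config <- function(score_fraction = 0.5, query_budget = Inf,
                          node_budget = Inf,
                          phases = c("ties", "boundary"),
                          dedup_representatives = FALSE) {
  stopifnot(score_fraction > 0, score_fraction <= 1,
            query_budget >= 0, node_budget >= 0,
            all(phases %in% c("ties", "boundary")))
  structure(list(score_fraction = score_fraction,
                 query_budget = query_budget,
                 node_budget = node_budget,
                 phases = phases,
                 dedup_representatives = dedup_representatives),
            class = "sscd_active_config")
}

#' Actively acquire must-link / cannot-link constraints
#'
#' Implements the three-phase active strategy. High-score nodes are
#' clustered locally ([partition_into_clusters()]) and the cluster
#' representatives are queried pairwise (phase 0). Phase `"ties"` then
#' queries, cluster by cluster in descending representative degree, every
#' member sharing its representative's maximal degree; a member answering
#' cannot-link is re-queried against the other representatives and joins the
#' first must-link cluster, or founds a new cluster (becoming its
#' representative) if all answers are cannot-link. Phase `"boundary"` visits
#' clusters round-robin in descending size and queries each cluster's
#' maximal-degree boundary member (one with an edge into another cluster)
#' the same way. The constraint store is updated after every single query,
#' and acquisition stops as soon as the query or node budget would be
#' exceeded.
#'
#' @param net an [network()] object.
#' @param oracle an [make_oracle()] whose truth covers `net`'s nodes.
#' @param cfg an [active_config()].
#' @return A list with `store` (the acquired [constraint_store()]),
#'   `clusters` (final `sscd_clusters`), `selected` (distinct nodes
#'   involved in queries), and `log` (data frame: phase, u, v, response).
#' @examples
#' k <- load_fixture("karate")
#' res <- acquire_constraints(k$network, make_oracle(k$truth),
#'                            active_config(phases = character()))
#' res$selected   # "1" "34"
#' @export
acquire_constraints <- function(net, oracle, cfg = active_config()) {
  stopifnot(inherits(net, "sscd_network"), inherits(oracle, "sscd_oracle"))
  missing <- setdiff(net$nodes, names(oracle$truth$assignment))
  if (length(missing)) stop("oracle truth does not cover node(s): ",
                            paste(missing, collapse = ", "))
  d <- degrees(net)
  sc <- node_scores(net)

  cand <- extract_candidates(net, cfg$score_fraction)
  cs <- select_representatives(net, partition_into_clusters(net, cand))
  clusters <- cs$clusters
  reps <- cs$representatives

  if (isTRUE(cfg$dedup_representatives)) {
    ta <- oracle$truth$assignment
    keep <- rep(TRUE, length(reps))
    for (lab in unique(ta[reps])) {
      grp <- which(ta[reps] == lab)
      if (length(grp) < 2L) next
      w <- grp[order(-d[reps[grp]], -sc[reps[grp]], reps[grp],
                     method = "radix")][1L]
      lose <- setdiff(grp, w)
      clusters[[w]] <- unique(c(clusters[[w]], unlist(clusters[lose])))
      keep[lose] <- FALSE
    }
    clusters <- clusters[keep]
    reps <- reps[keep]
  }

  ml <- matrix(character(), ncol = 2L)
  cl <- matrix(character(), ncol = 2L)
  selected <- character()
  log <- list()
  exhausted <- FALSE

  can_query <- function(u, v) {
    if (length(log) >= cfg$query_budget) return(FALSE)
    new <- setdiff(c(u, v), selected)
    length(selected) + length(new) <= cfg$node_budget
  }
  do_query <- function(phase, u, v) {
    is_ml <- oracle_query(oracle, u, v)
    if (is_ml) ml <<- rbind(ml, c(u, v)) else cl <<- rbind(cl, c(u, v))
    selected <<- union(selected, c(u, v))
    log[[length(log) + 1L]] <<- data.frame(
      phase = phase, u = u, v = v,
      response = if (is_ml) "ML" else "CL")
    is_ml
  }
  # query u against representatives other than `own`; returns index of the
  # cluster joined, 0 if all answers were cannot-link, NA on budget stop
  requery_other_reps <- function(phase, u, own) {
    others <- setdiff(seq_along(reps), own)
    others <- others[order(-d[reps[others]], reps[others], method = "radix")]
    for (j in others) {
      if (!can_query(u, reps[[j]])) { exhausted <<- TRUE; return(NA_integer_) }
      if (do_query(phase, u, reps[[j]])) return(j)
    }
    0L
  }

  # phase 0: all representative pairs, descending min degree of the pair
  if (length(reps) > 1L) {
    pairs <- t(utils::combn(seq_along(reps), 2L))
    dm <- cbind(pmin(d[reps[pairs[, 1L]]], d[reps[pairs[, 2L]]]),
                pmax(d[reps[pairs[, 1L]]], d[reps[pairs[, 2L]]]))
    pairs <- pairs[order(-dm[, 1L], -dm[, 2L], reps[pairs[, 1L]],
                         reps[pairs[, 2L]], method = "radix"), ,
                   drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      u <- reps[[pairs[r, 1L]]]; v <- reps[[pairs[r, 2L]]]
      if (!can_query(u, v)) { exhausted <- TRUE; break }
      do_query("representatives", u, v)
    }
  }

  # phase 1: members tying their representative's maximal degree
  if (!exhausted && "ties" %in% cfg$phases) {
    snapshot <- seq_along(clusters)
    snapshot <- snapshot[order(-d[reps[snapshot]], reps[snapshot],
                               method = "radix")]
    for (i in snapshot) {
      if (exhausted) break
      members <- setdiff(clusters[[i]], reps[[i]])
      ties <- members[d[members] == d[[reps[[i]]]]]
      ties <- ties[order(-sc[ties], ties, method = "radix")]
      for (u in ties) {
        if (!can_query(u, reps[[i]])) { exhausted <- TRUE; break }
        if (do_query("ties", u, reps[[i]])) next
        clusters[[i]] <- setdiff(clusters[[i]], u)
        j <- requery_other_reps("ties", u, i)
        if (is.na(j)) break
        if (j > 0L) {
          clusters[[j]] <- c(clusters[[j]], u)
        } else {
          clusters[[length(clusters) + 1L]] <- u
          reps <- c(reps, u)
        }
      }
    }
  }

  # phase 2: boundary members, clusters round-robin by descending size
  if (!exhausted && "boundary" %in% cfg$phases) {
    queried <- character()
    repeat {
      ord <- order(-vapply(clusters, length, integer(1L)),
                   reps, method = "radix")
      any_query <- FALSE
      for (i in ord) {
        if (exhausted) break
        pool <- setdiff(clusters[[i]], c(reps[[i]], queried))
        others <- unlist(clusters[-i], use.names = FALSE)
        bd <- pool[vapply(pool, function(w) any(net$adj[[w]] %in% others),
                          logical(1L))]
        if (length(bd) == 0L) next
        b <- bd[order(-d[bd], -sc[bd], bd, method = "radix")][1L]
        if (!can_query(b, reps[[i]])) { exhausted <- TRUE; break }
        queried <- c(queried, b)
        any_query <- TRUE
        if (do_query("boundary", b, reps[[i]])) next
        clusters[[i]] <- setdiff(clusters[[i]], b)
        j <- requery_other_reps("boundary", b, i)
        if (is.na(j)) break
        if (j > 0L) {
          clusters[[j]] <- c(clusters[[j]], b)
        } else {
          clusters[[length(clusters) + 1L]] <- b
          reps <- c(reps, b)
        }
      }
      if (exhausted || !any_query) break
    }
  }

  store <- constraint_store(must_link = ml, cannot_link = cl)
  chk <- check_consistency(store)
  if (!chk$ok) stop("internal error: noiseless oracle produced an ",
                    "inconsistent constraint store")
  out_clusters <- structure(list(clusters = clusters,
                                 representatives = reps),
                            class = "sscd_clusters")
  list(store = store,
       clusters = out_clusters,
       selected = sort(selected, method = "radix"),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(phase = character(), u = character(),
                    v = character(), response = character()))
}
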