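#' Simulate a single random walk
#'
#' The walker starts at `start` and at each of `l` steps moves to a neighbor
#' of the current node chosen uniformly at random. The record kept is the
#' *set* of distinct nodes visited (including the start), not the step
#' sequence: revisits do not accumulate.
#'
#' @param net an [network()] object.
#' @param start start node id.
#' @param l number of steps (`>= 0`).
#' @return A list with `start` and `visited` (sorted character vector `W`).
#' @examples
#' net <- network(cbind("u", "v"))
#' withr::with_seed(1, simulate_walk(net, "u", 3)$visited)
#' @export
simulate_walk <- function(net, start, l) {
  if (!start %in% net$nodes) stop("start node '", start, "' not in network")
  if (l < 0L) stop("walk length must be nonnegative")
  idx <- walk_indices(net)
  w <- walk_once(idx$adj, match(start, net$nodes), as.integer(l))
  if (l > 0L && length(w) == 1L && length(idx$adj[[w]]) == 0L) {
    warning("node '", start, "' has no neighbors; walk stays put",
            call. = FALSE)
  }
  list(start = start, visited = net$nodes[w])
}

# integer adjacency for fast walking
walk_indices <- function(net) {
  adj <- lapply(net$adj, match, net$nodes)
  list(adj = adj)
}

walk_once <- function(adj_int, start_i, l) {
  visited <- rep(FALSE, length(adj_int))
  visited[start_i] <- TRUE
  cur <- start_i
  if (l > 0L) {
    for (s in seq_len(l)) {
      nb <- adj_int[[cur]]
      if (length(nb) == 0L) break
      cur <- nb[[sample.int(length(nb), 1L)]]
      visited[cur] <- TRUE
    }
  }
  which(visited)
}

#' Compute random-walk co-visitation similarity
#'
#' Every node is taken in turn as the start of `walks_per_node` random walks
#' of `l` steps. After each walk the similarity count of every unordered
#' pair of distinct nodes in the walk's visited set is incremented by one.
#' The resulting symmetric integer matrix is a global similarity: pairs that
#' random walkers tend to co-visit — typically pairs inside the same densely
#' connected region — accumulate higher counts.
#'
#' @param net an [network()] object; a warning is emitted if disconnected.
#' @param l walk length in steps; defaults to `n = |V|`, long enough in
#'   principle for a walker to traverse the whole network.
#' @param walks_per_node walks started from each node (default 1).
#' @param seed optional seed applied locally (the caller's RNG state is
#'   restored).
#' @return An `sscd_similarity` object: an `n x n` symmetric numeric matrix
#'   of counts with node ids as dimnames, zero diagonal, and attributes
#'   `l` and `walks_per_node`.
#' @examples
#' net <- network(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' S <- compute_similarity(net, seed = 7)
#' @export
compute_similarity <- function(net, l = net$n, walks_per_node = 1L,
                               seed = NULL) {
  stopifnot(inherits(net, "sscd_network"))
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  if (!network_connected(net)) {
    warning("network is disconnected; walks cannot cross components",
            call. = FALSE)
  }
  idx <- walk_indices(net)
  n <- net$n
  S <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  l <- as.integer(l)
  for (start_i in seq_len(n)) {
    for (rep in seq_len(walks_per_node)) {
      w <- walk_once(idx$adj, start_i, l)
      if (length(w) > 1L) S[w, w] <- S[w, w] + 1
    }
  }
  diag(S) <- 0
  structure(S, l = l, walks_per_node = as.integer(walks_per_node),
            class = c("sscd_similarity", class(S)))
}

network_connected <- function(net) {
  if (net$n <= 1L) return(TRUE)
  idx <- walk_indices(net)
  seen <- rep(FALSE, net$n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    nb <- idx$adj[[cur]][!seen[idx$adj[[cur]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Similarity between a community and a node
#'
#' Defined as the maximum similarity between `v` and any member of the
#' community.
#'
#' @param S an `sscd_similarity` matrix (or any symmetric matrix with node
#'   dimnames).
#' @param community character vector of member node ids (non-empty).
#' @param v a node id not in `community`.
#' @return The maximal `s(u, v)` over `u` in the community.
#' @export
community_similarity <- function(S, community, v) {
  if (length(community) == 0L) stop("community must be non-empty")
  if (v %in% community) stop("node '", v, "' is already in the community")
  max(S[community, v])
}

#' Write / read a similarity matrix as TSV
#'
#' Plain-text cache: one `u<TAB>v<TAB>count` line per pair with a positive
#' count.
#'
#' @param S an `sscd_similarity` matrix.
#' @param path file path.
#' @return `write_similarity` returns `path` invisibly; `read_similarity`
#'   returns a symmetric matrix with the stored counts.
#' @param nodes node ids of the full matrix (pairs absent from the file get
#'   count 0).
#' @export
write_similarity <- function(S, path) {
  nodes <- rownames(S)
  ut <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(nodes[ut[, 1L]], nodes[ut[, 2L]], S[ut], sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path, nodes) {
  S <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  lines <- strip_comments(readLines(path, warn = FALSE))
  if (length(lines)) {
    toks <- strsplit(lines, "\t", fixed = TRUE)
    u <- vapply(toks, `[[`, character(1L), 1L)
    v <- vapply(toks, `[[`, character(1L), 2L)
    cnt <- as.numeric(vapply(toks, `[[`, character(1L), 3L))
    S[cbind(u, v)] <- cnt
    S[cbind(v, u)] <- cnt
  }
  S
}
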