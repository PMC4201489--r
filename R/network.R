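#' Construct a network from an edge list
#'
#' A network is a simple, undirected, unweighted graph: no self-loops, no
#' parallel edges. Node identifiers are opaque strings; numeric-looking ids
#' are not coerced.
#'
#' @param edges two-column character matrix (or data frame) of endpoints,
#'   one edge per row.
#' @param nodes optional character vector of node ids; defaults to the ids
#'   seen in `edges`. Extra ids become isolated nodes.
#' @return An object of class `sscd_network` with components `nodes` (sorted
#'   character vector), `edges` (two-column character matrix, endpoints
#'   sorted within each row), `adj` (named list: node -> character vector of
#'   neighbors), `n` and `m`.
#' @examples
#' net <- network(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' degrees(net)
#' @export
network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("edges must have two columns")
  edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- which(edges[, 1L] == edges[, 2L])[1L]
    stop("self-loop on node '", edges[bad, 1L], "' is not allowed")
  }
  # canonical unordered representation: endpoints sorted within each row
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      pr <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      warning("duplicate edge ", pr[1L], " -- ", pr[2L], " collapsed",
              call. = FALSE)
    }
    edges <- edges[!dup, , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))), method = "radix")
  adj <- lapply(stats::setNames(nodes, nodes), function(v) character())
  if (nrow(edges)) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    nb <- lapply(nb, sort, method = "radix")
    adj[names(nb)] <- nb
  }
  structure(
    list(nodes = nodes, edges = edges, adj = adj,
         n = length(nodes), m = nrow(edges)),
    class = "sscd_network"
  )
}

#' @export
print.sscd_network <- function(x, ...) {
  cat("<sscd_network> ", x$n, " nodes, ", x$m, " edges\n", sep = "")
  invisible(x)
}

#' Node degrees
#'
#' @param net an [network()] object.
#' @param v nodes to report; default all.
#' @return Named integer vector of degrees d(v) = |Gamma(v)|.
#' @export
degrees <- function(net, v = net$nodes) {
  vapply(net$adj[v], length, integer(1L))
}

#' Neighbor set
#'
#' @param net an [network()] object.
#' @param v a single node id.
#' @return Character vector Gamma(v) of neighbors of `v`.
#' @export
neighbors_of <- function(net, v) {
  if (!v %in% net$nodes) stop("node '", v, "' not in network")
  net$adj[[v]]
}

#' Construct a partition (community structure)
#'
#' Communities are pairwise disjoint, non-empty, and jointly cover the node
#' set.
#'
#' @param assignment named character vector: node id -> community label.
#' @return Object of class `sscd_partition` with components `assignment`
#'   (sorted by node id), `communities` (label -> character vector of
#'   members) and `k`.
#' @examples
#' p <- partition(c(a = "1", b = "1", c = "2"))
#' p$k
#' @export
partition <- function(assignment) {
  if (length(assignment) == 0L) stop("a partition must contain at least one node")
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("assignment must be a named vector (node -> label)")
  }
  if (anyDuplicated(names(assignment))) {
    d <- names(assignment)[duplicated(names(assignment))][1L]
    stop("node '", d, "' assigned more than once")
  }
  assignment <- vapply(assignment, as.character, character(1L))
  if (any(is.na(assignment) | assignment == "")) stop("blank community label")
  assignment <- assignment[sort(names(assignment), method = "radix")]
  communities <- split(names(assignment), assignment)
  structure(
    list(assignment = assignment, communities = communities,
         k = length(communities)),
    class = "sscd_partition"
  )
}

#' @export
print.sscd_partition <- function(x, ...) {
  cat("<sscd_partition> ", length(x$assignment), " nodes in ", x$k,
      " communities\n", sep = "")
  invisible(x)
}

strip_comments <- function(lines) {
  lines <- trimws(lines)
  lines[!(lines == "" | startsWith(lines, "#"))]
}

#' Read a network from a plain-text edge list
#'
#' One edge per line, the first two whitespace-separated tokens being the
#' endpoint ids. Lines starting with `#` and blank lines are ignored.
#' Duplicate edges are collapsed with a warning; self-loops are an error.
#'
#' @param path path to the edge-list file.
#' @return An [network()] object.
#' @export
read_edge_list <- function(path) {
  lines <- strip_comments(readLines(path, warn = FALSE))
  if (length(lines) == 0L) stop("no edges in '", path, "'")
  toks <- strsplit(lines, "[ \t]+")
  short <- vapply(toks, length, integer(1L)) < 2L
  if (any(short)) {
    stop("line ", which(short)[1L], " of '", path,
         "' does not contain two node ids")
  }
  u <- vapply(toks, `[[`, character(1L), 1L)
  v <- vapply(toks, `[[`, character(1L), 2L)
  loop <- u == v
  if (any(loop)) {
    stop("self-loop '", lines[which(loop)[1L]], "' at line ",
         which(loop)[1L], " of '", path, "'")
  }
  network(cbind(u, v))
}

#' Read a node-membership file as a partition
#'
#' Each line holds a node id and a community label separated by whitespace
#' (tab or spaces). Conflicting duplicate assignments are an error.
#'
#' @param path path to the membership file.
#' @return An [partition()] object.
#' @export
read_membership <- function(path) {
  lines <- strip_comments(readLines(path, warn = FALSE))
  if (length(lines) == 0L) stop("no memberships in '", path, "'")
  toks <- strsplit(lines, "[ \t]+")
  short <- vapply(toks, length, integer(1L)) < 2L
  if (any(short)) {
    stop("line ", which(short)[1L], " of '", path, "' lacks a label")
  }
  node <- vapply(toks, `[[`, character(1L), 1L)
  lab <- vapply(toks, `[[`, character(1L), 2L)
  for (nd in unique(node[duplicated(node)])) {
    if (length(unique(lab[node == nd])) > 1L) {
      stop("node '", nd, "' has conflicting community labels")
    }
  }
  keep <- !duplicated(node)
  partition(stats::setNames(lab[keep], node[keep]))
}

#' Write a partition to a membership file
#'
#' Output is one `node<TAB>label` line per node, nodes sorted
#' lexicographically, UTF-8, LF line endings; readable by
#' [read_membership()].
#'
#' @param p an [partition()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_membership <- function(p, path) {
  stopifnot(inherits(p, "sscd_partition"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(p$assignment), p$assignment, sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' Load a bundled benchmark network with its ground truth
#'
#' The Zachary karate club network (34 nodes, 78 edges, two factions) ships
#' with the package. The other classic benchmarks used alongside it in the
#' literature (Lusseau's dolphin social network, the Risk board-game map,
#' and the Santa Fe Institute collaboration network) are not redistributed
#' here; asking for them produces an error pointing at their original
#' sources. Synthetic presets (`"planted4"`) generate a planted-partition
#' benchmark on the fly.
#'
#' @param name one of `"karate"`, `"planted4"` (four blocks of 25,
#'   `p_in = 0.3`, `p_out = 0.02`), `"dolphin"`, `"risk"`,
#'   `"collaboration"`.
#' @param seed seed used by synthetic presets.
#' @return A list with components `network` and `truth` (a [partition()]).
#' @examples
#' k <- load_fixture("karate")
#' k$network$n
#' @export
load_fixture <- function(name, seed = 1L) {
  switch(
    name,
    karate = {
      ext <- system.file("extdata", package = "sscd")
      list(network = read_edge_list(file.path(ext, "karate_edges.txt")),
           truth = read_membership(file.path(ext, "karate_factions.tsv")))
    },
    planted4 = {
      g <- generate_planted_partition(sizes = rep(25L, 4L), p_in = 0.3,
                                      p_out = 0.02, seed = seed,
                                      require_connected = TRUE)
      list(network = g$network, truth = g$truth)
    },
    dolphin = ,
    risk = ,
    collaboration = stop(
      "fixture '", name, "' is not bundled with this package; ",
      "obtain the original data (dolphin: Lusseau et al. 2003; risk: the ",
      "Risk board-game territory map; collaboration: the Santa Fe Institute ",
      "collaboration network of Girvan & Newman 2002) and load it with ",
      "read_edge_list()/read_membership()"
    ),
    stop("unknown fixture '", name, "'; available: karate, planted4 ",
         "(dolphin, risk, collaboration must be supplied externally)")
  )
}
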