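#' Modularity of a partition
#'
#' Newman–Girvan modularity computed from the community mixing matrix `e`:
#' `e_ii` is the fraction of edges with both endpoints in community `i`, a
#' cross edge between communities `i` and `j` contributes `1/(2m)` to both
#' `e_ij` and `e_ji`, and `a_i` are the row sums. The score is
#' `Q = sum_i (e_ii - a_i^2)`: the intra-community edge fraction minus its
#' expectation in a degree-preserving random graph. `Q` near 0 means no more
#' internal structure than random; values above roughly 0.3 indicate
#' significant community structure.
#'
#' @param net an [network()] object.
#' @param p an [partition()] covering exactly the nodes of `net`.
#' @return The modularity `Q` (a number in `[-1, 1]`).
#' @examples
#' k <- load_fixture("karate")
#' modularity_q(k$network, k$truth)   # 0.371
#' @export
modularity_q <- function(net, p) {
  stopifnot(inherits(net, "sscd_network"), inherits(p, "sscd_partition"))
  if (!setequal(names(p$assignment), net$nodes)) {
    stop("partition must cover exactly the network's nodes")
  }
  if (net$m == 0L) stop("modularity is undefined for an empty edge set")
  labs <- sort(unique(p$assignment), method = "radix")
  k <- length(labs)
  ci <- match(p$assignment[net$edges[, 1L]], labs)
  cj <- match(p$assignment[net$edges[, 2L]], labs)
  e <- matrix(0, k, k)
  m <- net$m
  for (r in seq_along(ci)) {
    if (ci[r] == cj[r]) {
      e[ci[r], ci[r]] <- e[ci[r], ci[r]] + 1 / m
    } else {
      e[ci[r], cj[r]] <- e[ci[r], cj[r]] + 1 / (2 * m)
      e[cj[r], ci[r]] <- e[cj[r], ci[r]] + 1 / (2 * m)
    }
  }
  a <- rowSums(e)
  sum(diag(e) - a^2)
}

#' Match extracted community labels to ground-truth labels
#'
#' Each extracted community takes the ground-truth label occurring most
#' frequently among its members. When several communities claim the same
#' label, the one with the most nodes of that label keeps it; each loser
#' falls back to its next-most-frequent remaining label or, with no label
#' left, is removed (all its members count as misclassified). The procedure
#' iterates until the surviving labels are unique. Frequency ties break
#' toward the label whose ground-truth community is larger, then toward the
#' community containing the smallest node id, so the matching depends only
#' on the partition structure and never on how communities happen to be
#' named.
#'
#' @param truth,pred two [partition()]s over the same node set.
#' @return A list with `matching` (named character vector: extracted
#'   community label -> truth label, `NA` for removed communities) and
#'   `predicted` (named character vector: node -> matched truth label, `NA`
#'   for members of removed communities).
#' @export
match_labels <- function(truth, pred) {
  stopifnot(inherits(truth, "sscd_partition"), inherits(pred, "sscd_partition"))
  if (!setequal(names(truth$assignment), names(pred$assignment))) {
    stop("partitions must cover the same node set")
  }
  truth_sizes <- vapply(truth$communities, length, integer(1L))
  # name-free tie-break keys: the smallest member id of each community
  truth_minid <- vapply(truth$communities, function(mm)
    min(sort(mm, method = "radix")), character(1L))
  pred_minid <- vapply(pred$communities, function(mm)
    min(sort(mm, method = "radix")), character(1L))
  # per extracted community: truth labels ranked by count desc, then
  # truth-community size desc, then the truth community's smallest member
  prefs <- lapply(pred$communities, function(members) {
    tab <- table(truth$assignment[members])
    lab <- names(tab)
    cnt <- as.integer(tab)
    ord <- order(-cnt, -truth_sizes[lab], truth_minid[lab], method = "radix")
    list(labels = lab[ord], counts = cnt[ord])
  })
  comm <- names(pred$communities)
  ptr <- stats::setNames(rep(1L, length(comm)), comm)   # preference pointer
  alive <- stats::setNames(rep(TRUE, length(comm)), comm)
  current <- function(cm) {
    if (!alive[[cm]]) return(NA_character_)
    prefs[[cm]]$labels[[ptr[[cm]]]]
  }
  repeat {
    labs <- vapply(comm, current, character(1L))
    dup_labs <- unique(labs[!is.na(labs)][duplicated(labs[!is.na(labs)])])
    if (length(dup_labs) == 0L) break
    for (L in dup_labs) {
      claimants <- comm[!is.na(labs) & labs == L]
      cnts <- vapply(claimants, function(cm) prefs[[cm]]$counts[[ptr[[cm]]]],
                     integer(1L))
      szs <- vapply(claimants, function(cm) length(pred$communities[[cm]]),
                    integer(1L))
      winner <- claimants[order(-cnts, -szs, pred_minid[claimants],
                                method = "radix")][1L]
      for (cm in setdiff(claimants, winner)) {
        if (ptr[[cm]] < length(prefs[[cm]]$labels)) {
          ptr[[cm]] <- ptr[[cm]] + 1L
        } else {
          alive[[cm]] <- FALSE
        }
      }
    }
  }
  matching <- vapply(comm, current, character(1L))
  predicted <- matching[pred$assignment]
  names(predicted) <- names(pred$assignment)
  list(matching = matching, predicted = predicted)
}

#' Clustering accuracy against a ground truth
#'
#' The fraction of nodes whose matched predicted label (see
#' [match_labels()]) equals their ground-truth label. Members of removed
#' (unmatched) communities count as misclassified.
#'
#' @inheritParams match_labels
#' @return Accuracy `A` in `[0, 1]`.
#' @examples
#' t <- partition(c(a = "X", b = "X", c = "Y"))
#' accuracy(t, t)   # 1
#' @export
accuracy <- function(truth, pred) {
  m <- match_labels(truth, pred)
  pl <- m$predicted[names(truth$assignment)]
  mean(!is.na(pl) & pl == truth$assignment)
}

#' Misclassified nodes under the label matching
#'
#' @inheritParams match_labels
#' @return Character vector of node ids whose matched label differs from
#'   their truth label.
#' @export
misclassified_nodes <- function(truth, pred) {
  m <- match_labels(truth, pred)
  pl <- m$predicted[names(truth$assignment)]
  names(truth$assignment)[is.na(pl) | pl != truth$assignment]
}

#' Normalized mutual information between two partitions
#'
#' Plug-in mutual information between the community labelings, normalized by
#' `sqrt(H(A) * H(B))` (natural logarithms; the base cancels). Identical
#' partitions score 1, independent labelings 0. Degenerate single-community
#' cases: both single -> 1; exactly one single (zero entropy) -> 0.
#'
#' @inheritParams match_labels
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  stopifnot(inherits(truth, "sscd_partition"), inherits(pred, "sscd_partition"))
  nodes <- names(truth$assignment)
  if (!setequal(nodes, names(pred$assignment))) {
    stop("partitions must cover the same node set")
  }
  n <- length(nodes)
  N <- table(truth$assignment[nodes], pred$assignment[nodes])
  pa <- rowSums(N) / n
  pb <- colSums(N) / n
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pj <- N / n
  nz <- pj > 0
  I <- sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
  max(0, min(1, I / sqrt(ha * hb)))
}

#' Evaluate a predicted partition against the truth
#'
#' Convenience wrapper reporting modularity, accuracy, NMI and the
#' misclassified nodes in one call.
#'
#' @param net an [network()] object.
#' @inheritParams match_labels
#' @return A list with `Q`, `A`, `NMI` and `misclassified`.
#' @export
evaluate_partition <- function(net, truth, pred) {
  list(Q = modularity_q(net, pred),
       A = accuracy(truth, pred),
       NMI = nmi(truth, pred),
       misclassified = misclassified_nodes(truth, pred))
}
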