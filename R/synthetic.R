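#' Generate a planted-partition benchmark network
#'
#' Nodes are divided into blocks; each intra-block pair becomes an edge with
#' probability `p_in`, each inter-block pair with probability `p_out`
#' (`p_out < p_in`), giving the dense-inside / sparse-between structure that
#' community detection assumes. The blocks are returned as the ground-truth
#' partition, so the generator also backs a noiseless oracle.
#'
#' @param sizes integer vector of block sizes (all positive, total `>= 2`).
#' @param p_in intra-block edge probability.
#' @param p_out inter-block edge probability, `0 <= p_out < p_in <= 1`.
#' @param seed optional seed applied locally.
#' @param require_connected resample (up to 100 attempts) until the network
#'   is connected; error if unattainable.
#' @return A list with `network` (an [network()]) and `truth` (an
#'   [partition()] with labels `b1`, `b2`, ...). Node ids are zero-padded
#'   `n001`, `n002`, ... in block order.
#' @examples
#' g <- generate_planted_partition(c(3, 3), p_in = 1, p_out = 0)
#' g$truth$k
#' @export
generate_planted_partition <- function(sizes, p_in, p_out, seed = NULL,
                                       require_connected = FALSE) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1L), sum(sizes) >= 2L,
            p_out >= 0, p_out <= p_in, p_in <= 1)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  n <- sum(sizes)
  ids <- sprintf("n%0*d", nchar(n), seq_len(n))
  block <- rep(seq_along(sizes), sizes)
  truth <- partition(stats::setNames(paste0("b", block), ids))

  pr <- utils::combn(n, 2L)
  p <- ifelse(block[pr[1L, ]] == block[pr[2L, ]], p_in, p_out)
  sample_net <- function() {
    keep <- stats::runif(ncol(pr)) < p
    network(cbind(ids[pr[1L, keep]], ids[pr[2L, keep]]), nodes = ids)
  }
  net <- sample_net()
  if (require_connected) {
    attempt <- 1L
    while (!network_connected(net)) {
      if (attempt >= 100L) {
        stop("could not generate a connected network in 100 attempts ",
             "(n = ", n, ", p_in = ", p_in, ", p_out = ", p_out, "); ",
             "increase the edge probabilities or block sizes")
      }
      attempt <- attempt + 1L
      net <- sample_net()
    }
  }
  list(network = net, truth = truth)
}
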