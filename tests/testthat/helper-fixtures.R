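# small graphs and independent reference implementations used across tests

triangle_net <- function() network(cbind(c("a", "b", "c"), c("b", "c", "a")))

path_net <- function(ids = c("a", "b", "c")) {
  network(cbind(ids[-length(ids)], ids[-1L]))
}

# two triangles joined by a single bridge edge
barbell_net <- function() {
  network(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                c("x", "y"), c("y", "z"), c("z", "x"),
                c("a", "x")))
}

complete_net <- function(ids) {
  network(t(utils::combn(ids, 2L)))
}

random_net <- function(n, p, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("v%02d", seq_len(n))
    pr <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(pr)) < p
    if (!any(keep)) keep[1L] <- TRUE
    network(cbind(ids[pr[1L, keep]], ids[pr[2L, keep]]), nodes = ids)
  })
}

random_partition <- function(nodes, k, seed) {
  withr::with_seed(seed, {
    lab <- paste0("g", c(seq_len(k), sample.int(k, length(nodes) - k,
                                                replace = TRUE)))
    partition(stats::setNames(sample(lab), nodes))
  })
}

# brute-force constraint closure: saturate the two inference rules
# (ML transitivity; CL across an ML edge) by fixpoint iteration
brute_force_closure <- function(ml, cl) {
  key <- function(p) paste(pmin(p[, 1L], p[, 2L]), pmax(p[, 1L], p[, 2L]))
  as_set <- function(p) if (nrow(p)) unique(key(p)) else character()
  mlk <- as_set(ml)
  clk <- as_set(cl)
  split_key <- function(kk) do.call(rbind, strsplit(kk, " ", fixed = TRUE))
  repeat {
    changed <- FALSE
    mlp <- if (length(mlk)) split_key(mlk) else matrix(character(), ncol = 2L)
    # ML transitivity
    if (nrow(mlp) > 1L) {
      for (i in seq_len(nrow(mlp))) for (j in seq_len(nrow(mlp))) {
        shared <- intersect(mlp[i, ], mlp[j, ])
        if (length(shared) == 1L) {
          oth <- c(setdiff(mlp[i, ], shared), setdiff(mlp[j, ], shared))
          if (oth[1L] != oth[2L]) {
            kk <- paste(min(oth), max(oth))
            if (!kk %in% mlk) { mlk <- c(mlk, kk); changed <- TRUE }
          }
        }
      }
    }
    # CL propagation along ML
    clp <- if (length(clk)) split_key(clk) else matrix(character(), ncol = 2L)
    if (nrow(clp) && nrow(mlp)) {
      for (i in seq_len(nrow(clp))) for (j in seq_len(nrow(mlp))) {
        shared <- intersect(clp[i, ], mlp[j, ])
        for (s in shared) {
          a <- setdiff(clp[i, ], s)
          b <- setdiff(mlp[j, ], s)
          if (length(a) == 1L && length(b) == 1L && a != b) {
            kk <- paste(min(c(a, b)), max(c(a, b)))
            if (!kk %in% clk) { clk <- c(clk, kk); changed <- TRUE }
          }
        }
      }
    }
    if (!changed) break
  }
  list(ml = sort(mlk), cl = sort(clk))
}

store_keys <- function(store) {
  key <- function(p) if (nrow(p)) sort(paste(p[, 1L], p[, 2L])) else character()
  list(ml = key(store$must_link), cl = key(store$cannot_link))
}

# degree-based modularity: Q = (1/2m) sum_uv (A_uv - d_u d_v / 2m) delta(c_u c_v)
modularity_degree_form <- function(net, p) {
  m <- net$m
  d <- degrees(net)
  lab <- p$assignment
  intra <- sum(lab[net$edges[, 1L]] == lab[net$edges[, 2L]]) / m
  expect <- 0
  for (cc in p$communities) {
    expect <- expect + (sum(d[cc]) / (2 * m))^2
  }
  intra - expect
}

relabel_partition <- function(p, seed) {
  withr::with_seed(seed, {
    labs <- unique(p$assignment)
    new <- stats::setNames(paste0("z", sample(seq_along(labs))), labs)
    partition(stats::setNames(new[p$assignment], names(p$assignment)))
  })
}
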