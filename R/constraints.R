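canonical_pairs <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) return(matrix(character(), ncol = 2L))
  pairs <- cbind(as.character(pairs[, 1L]), as.character(pairs[, 2L]))
  if (any(pairs[, 1L] == pairs[, 2L])) {
    stop("constraint pairs must reference two distinct nodes")
  }
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, c(2L, 1L), drop = FALSE]
  pairs[!duplicated(paste(pairs[, 1L], pairs[, 2L], sep = "\r")), ,
        drop = FALSE]
}

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character())
  paste(pairs[, 1L], pairs[, 2L], sep = "\r")
}

#' Build a must-link / cannot-link constraint store
#'
#' Pairs are unordered: `(u, v)` and `(v, u)` denote the same constraint.
#'
#' @param must_link,cannot_link two-column character matrices (or data
#'   frames) of node pairs; may be empty.
#' @return Object of class `sscd_constraints` with canonicalized `must_link`
#'   and `cannot_link` pair matrices and a `closed` flag.
#' @examples
#' st <- constraint_store(must_link = rbind(c("1", "2")),
#'                        cannot_link = rbind(c("1", "34")))
#' @export
constraint_store <- function(must_link = NULL, cannot_link = NULL) {
  ml <- canonical_pairs(if (is.null(must_link)) matrix(character(), ncol = 2L) else must_link)
  cl <- canonical_pairs(if (is.null(cannot_link)) matrix(character(), ncol = 2L) else cannot_link)
  structure(list(must_link = ml, cannot_link = cl, closed = FALSE),
            class = "sscd_constraints")
}

#' @export
print.sscd_constraints <- function(x, ...) {
  cat("<sscd_constraints> ", nrow(x$must_link), " must-link, ",
      nrow(x$cannot_link), " cannot-link",
      if (isTRUE(x$closed)) " (closed)", "\n", sep = "")
  invisible(x)
}

# union-find over the nodes touched by the must-link set; returns a named
# integer vector node -> group id
ml_groups <- function(store) {
  nodes <- sort(unique(c(as.vector(store$must_link),
                         as.vector(store$cannot_link))), method = "radix")
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(store$must_link)) {
    ia <- match(store$must_link[, 1L], nodes)
    ib <- match(store$must_link[, 2L], nodes)
    for (r in seq_along(ia)) {
      ra <- find(ia[r]); rb <- find(ib[r])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1L))
  stats::setNames(match(roots, unique(roots)), nodes)
}

#' Transitively close a constraint set
#'
#' Must-links define a transitive relation: chaining them yields every pair
#' within each must-link group. Combining a cannot-link `(a, b)` with
#' must-links then implies a cannot-link between every member of `a`'s group
#' and every member of `b`'s group.
#'
#' @param store an [constraint_store()].
#' @return A closed `sscd_constraints` store (idempotent).
#' @examples
#' st <- constraint_store(rbind(c("1", "2"), c("2", "3")))
#' close_constraints(st)$must_link   # includes ("1", "3")
#' @export
close_constraints <- function(store) {
  stopifnot(inherits(store, "sscd_constraints"))
  grp <- ml_groups(store)
  members <- split(names(grp), grp)
  ml <- do.call(rbind, lapply(members, function(mm) {
    if (length(mm) < 2L) return(NULL)
    t(utils::combn(sort(mm, method = "radix"), 2L))
  }))
  if (is.null(ml)) ml <- matrix(character(), ncol = 2L)
  cl <- store$cannot_link
  if (nrow(cl)) {
    expanded <- lapply(seq_len(nrow(cl)), function(r) {
      ga <- members[[grp[cl[r, 1L]]]]
      gb <- members[[grp[cl[r, 2L]]]]
      out <- cbind(rep(ga, each = length(gb)), rep(gb, length(ga)))
      # a cannot-link inside one must-link group (inconsistent input) would
      # expand to self-pairs; drop those and let check_consistency report
      # the remaining within-group conflicts
      out[out[, 1L] != out[, 2L], , drop = FALSE]
    })
    cl <- canonical_pairs(do.call(rbind, expanded))
  }
  out <- constraint_store(ml, cl)
  out$closed <- TRUE
  out
}

#' Check a closed constraint store for consistency
#'
#' A store is inconsistent when some pair is simultaneously must-link and
#' cannot-link after closure (e.g. a cannot-link inside a must-link group).
#'
#' @param store a closed [constraint_store()]; an unclosed store is closed
#'   first.
#' @return A list with `ok` (logical) and `conflicts` (two-column matrix of
#'   offending pairs, zero rows when consistent).
#' @export
check_consistency <- function(store) {
  if (!isTRUE(store$closed)) store <- close_constraints(store)
  clash <- pair_keys(store$cannot_link) %in% pair_keys(store$must_link)
  list(ok = !any(clash),
       conflicts = store$cannot_link[clash, , drop = FALSE])
}

#' Read constraints from a TSV file
#'
#' Format: `u<TAB>v<TAB>ML|CL`, one constraint per line; `#` comments
#' allowed.
#'
#' @param path path to the constraint file.
#' @return An (unclosed) [constraint_store()].
#' @export
read_constraints <- function(path) {
  lines <- strip_comments(readLines(path, warn = FALSE))
  if (length(lines) == 0L) return(constraint_store())
  toks <- strsplit(lines, "[ \t]+")
  bad <- vapply(toks, length, integer(1L)) < 3L
  if (any(bad)) stop("line ", which(bad)[1L], " of '", path,
                     "' is not 'u v ML|CL'")
  u <- vapply(toks, `[[`, character(1L), 1L)
  v <- vapply(toks, `[[`, character(1L), 2L)
  rel <- toupper(vapply(toks, `[[`, character(1L), 3L))
  if (!all(rel %in% c("ML", "CL"))) {
    stop("constraint relation must be ML or CL")
  }
  constraint_store(must_link = cbind(u, v)[rel == "ML", , drop = FALSE],
                   cannot_link = cbind(u, v)[rel == "CL", , drop = FALSE])
}

#' Write constraints to a TSV file
#'
#' @param store an [constraint_store()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_constraints <- function(store, path) {
  stopifnot(inherits(store, "sscd_constraints"))
  lines <- c(
    if (nrow(store$must_link))
      paste(store$must_link[, 1L], store$must_link[, 2L], "ML", sep = "\t"),
    if (nrow(store$cannot_link))
      paste(store$cannot_link[, 1L], store$cannot_link[, 2L], "CL", sep = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
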