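# ---- interaction container ---------------------------------------------
#
# An "interaction_set" is a data.frame with one row per order-k clique:
# member columns m1..mk (site row indices into attr(,"sites"), strictly
# increasing, which is the canonical (chain, seq_index) order because the
# site table is sorted that way), one distance column per member pair
# (d12, d13, ..., in combn order), and a span label. Attributes carry the
# order, site table, window and min_seq_sep.

.pair_labels <- function(order) {
  if (order < 2) return(character(0))
  p <- utils::combn(order, 2)
  paste0("d", p[1, ], p[2, ])
}

.new_interaction_set <- function(members, graph, order) {
  sites <- graph$sites
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  nr <- nrow(members)
  labs <- .pair_labels(order)
  if (nr == 0) {
    df <- as.data.frame(matrix(integer(0), ncol = order),
                        col.names = paste0("m", seq_len(order)))
    names(df) <- paste0("m", seq_len(order))
    for (l in labs) df[[l]] <- numeric(0)
    df$span <- character(0)
  } else {
    df <- as.data.frame(members)
    names(df) <- paste0("m", seq_len(order))
    p <- utils::combn(order, 2)
    for (c_idx in seq_len(ncol(p))) {
      df[[labs[c_idx]]] <- .site_dist(xyz, members[, p[1, c_idx]],
                                      members[, p[2, c_idx]])
    }
    ch <- matrix(sites$chain[members], nrow = nr)
    same <- rowSums(ch == ch[, 1]) == order
    df$span <- ifelse(same, "intra-chain", "inter-chain")
  }
  rownames(df) <- NULL
  class(df) <- c("interaction_set", "data.frame")
  attr(df, "order") <- as.integer(order)
  attr(df, "sites") <- sites
  attr(df, "window") <- graph$window
  attr(df, "min_seq_sep") <- graph$min_seq_sep
  df
}

#' @export
print.interaction_set <- function(x, n = 10, ...) {
  k <- attr(x, "order")
  w <- attr(x, "window")
  cat(sprintf("<%d interaction(s) of order %d, window [%.2f, %.2f] A>\n",
              nrow(x), k, w[1], w[2]))
  if (nrow(x) > 0) {
    shown <- utils::head(as.data.frame(format_interactions(x)), n)
    print(shown)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more row(s)\n")
  }
  invisible(x)
}

#' Human-readable member descriptors for an interaction set
#'
#' Replaces site indices by \code{CHAIN:RESNAME:RESNUM[:ICODE]} descriptors
#' and rounds distances for display.
#'
#' @param x an \code{"interaction_set"}.
#' @param digits decimal places for distances (default 2, the reporting
#'   precision).
#' @return plain data.frame with member descriptor columns, distance
#'   columns and span.
#' @export
format_interactions <- function(x, digits = 2) {
  stopifnot(inherits(x, "interaction_set"))
  k <- attr(x, "order")
  sites <- attr(x, "sites")
  desc <- function(idx) {
    if (length(idx) == 0) return(character(0))
    paste0(sites$chain[idx], ":", sites$resid[idx], ":", sites$resno[idx],
           ifelse(sites$insert[idx] == "", "",
                  paste0(":", sites$insert[idx])))
  }
  out <- data.frame(order = rep(k, nrow(x)))
  for (m in seq_len(k)) out[[paste0("member", m)]] <- desc(x[[paste0("m", m)]])
  for (l in .pair_labels(k))
    out[[l]] <- formatC(x[[l]], format = "f", digits = digits)
  out$span <- x$span
  out
}

# ---- enumeration --------------------------------------------------------

#' Enumerate pairwise interactions
#'
#' One order-2 interaction per contact edge, in canonical order.
#'
#' @param graph a \code{"contact_graph"}.
#' @return an \code{"interaction_set"} of order 2.
#' @export
enumerate_pairs <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  members <- cbind(graph$edges$i, graph$edges$j)
  .new_interaction_set(members, graph, 2L)
}

# triangles (i < j < k) of the graph as a 3-column matrix
.triangles <- function(graph, adj = .adjacency(graph)) {
  e <- graph$edges
  out <- list(); n_out <- 0L
  for (r in seq_len(nrow(e))) {
    i <- e$i[r]; j <- e$j[r]
    # ordered extension: common neighbours beyond j, so each triangle
    # appears exactly once with i < j < k
    ks <- intersect(adj[[i]][adj[[i]] > j], adj[[j]][adj[[j]] > j])
    if (length(ks) > 0) {
      n_out <- n_out + 1L
      out[[n_out]] <- cbind(i, j, ks)
    }
  }
  if (n_out == 0L) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

#' Enumerate triplet interactions
#'
#' Triplets are the triangles of the contact graph: three residues whose
#' three pairwise distances all lie in the window (mutual contact). Each
#' triangle is found once by extending each edge (i, j) with common
#' neighbours beyond j.
#'
#' @inheritParams enumerate_pairs
#' @return an \code{"interaction_set"} of order 3.
#' @export
enumerate_triplets <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  .new_interaction_set(.triangles(graph), graph, 3L)
}

#' Enumerate quadruplet interactions
#'
#' Quadruplets are the 4-cliques of the contact graph (all six member
#' pairs in contact), the largest mutual-contact set possible for
#' equal-sized spheres in three dimensions. Each 4-clique is found once by
#' extending each triangle (i, j, k) with common neighbours beyond k.
#'
#' @inheritParams enumerate_pairs
#' @return an \code{"interaction_set"} of order 4.
#' @export
enumerate_quadruplets <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  adj <- .adjacency(graph)
  tri <- .triangles(graph, adj)
  out <- list(); n_out <- 0L
  for (r in seq_len(nrow(tri))) {
    i <- tri[r, 1]; j <- tri[r, 2]; k <- tri[r, 3]
    ls <- intersect(intersect(adj[[i]][adj[[i]] > k], adj[[j]][adj[[j]] > k]),
                    adj[[k]][adj[[k]] > k])
    if (length(ls) > 0) {
      n_out <- n_out + 1L
      out[[n_out]] <- cbind(i, j, k, ls)
    }
  }
  members <- if (n_out == 0L) matrix(integer(0), ncol = 4) else {
    m <- do.call(rbind, out)
    m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
  }
  .new_interaction_set(members, graph, 4L)
}

#' Enumerate interactions at several orders
#'
#' @param graph a \code{"contact_graph"}.
#' @param orders integer subset of \code{c(2, 3, 4)}.
#' @return named list of \code{"interaction_set"} objects
#'   (\code{$pairs}, \code{$triplets}, \code{$quadruplets} as requested).
#' @export
enumerate_interactions <- function(graph, orders = c(2, 3, 4)) {
  stopifnot(inherits(graph, "contact_graph"), all(orders %in% 2:4))
  out <- list()
  if (2 %in% orders) out$pairs <- enumerate_pairs(graph)
  if (3 %in% orders) out$triplets <- enumerate_triplets(graph)
  if (4 %in% orders) out$quadruplets <- enumerate_quadruplets(graph)
  out
}

# member-index matrix of an interaction set
.members <- function(x) {
  k <- attr(x, "order")
  m <- as.matrix(as.data.frame(x)[, paste0("m", seq_len(k)), drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

# frozen member-key tuples ("A:12|A:15|B:3"), for set comparisons
.member_keys <- function(x) {
  sites <- attr(x, "sites")
  m <- .members(x)
  if (nrow(m) == 0) return(character(0))
  keys <- matrix(site_key(sites$chain[m], sites$resno[m], sites$insert[m]),
                 nrow = nrow(m))
  apply(keys, 1, paste, collapse = "|")
}
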