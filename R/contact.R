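#' Euclidean distance between two points
#'
#' @param a,b numeric 3-vectors (Angstrom).
#' @return distance in Angstrom.
#' @export
euclidean_distance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite coordinates")
  sqrt(sum((a - b)^2))
}

# distances between site rows i and j (vectorized, one shared code path so
# edge distances and interaction distances are bit-identical)
.site_dist <- function(xyz, i, j) {
  sqrt((xyz[i, 1] - xyz[j, 1])^2 +
       (xyz[i, 2] - xyz[j, 2])^2 +
       (xyz[i, 3] - xyz[j, 3])^2)
}

# Cell-list candidate pairs: all (i, j), i < j, within `cutoff` of each
# other are guaranteed to be returned (possibly with extras beyond cutoff).
# Sites are binned into cubic cells of edge >= cutoff; only the 13
# lexicographically "forward" neighbour offsets plus the home cell are
# scanned, so each pair is produced once.
.candidate_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(cbind(i = integer(0), j = integer(0)))
  spread <- max(apply(xyz, 2, function(v) diff(range(v))))
  # degenerate geometries (all points coincident, or a zero cutoff) fall
  # back to exhaustive all-pairs: correctness first
  if (!is.finite(cutoff) || cutoff <= 0 || spread == 0) {
    idx <- utils::combn(n, 2)
    return(cbind(i = idx[1, ], j = idx[2, ]))
  }
  bins <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  storage.mode(bins) <- "integer"
  # pack 3 bin indices into one numeric key
  dims <- apply(bins, 2, max) + 1L
  keyof <- function(b1, b2, b3) (as.numeric(b1) * dims[2] + b2) * dims[3] + b3
  key <- keyof(bins[, 1], bins[, 2], bins[, 3])
  cell <- split(seq_len(n), key)
  occupied <- unique(bins)
  okey <- keyof(occupied[, 1], occupied[, 2], occupied[, 3])
  offsets <- rbind(
    c(1, -1, -1), c(1, -1, 0), c(1, -1, 1),
    c(1,  0, -1), c(1,  0, 0), c(1,  0, 1),
    c(1,  1, -1), c(1,  1, 0), c(1,  1, 1),
    c(0,  1, -1), c(0,  1, 0), c(0,  1, 1),
    c(0,  0,  1))
  ii <- list(); jj <- list(); k <- 0L
  for (c_idx in seq_along(okey)) {
    home <- cell[[as.character(okey[c_idx])]]
    if (length(home) > 1) {
      p <- utils::combn(home, 2)
      k <- k + 1L; ii[[k]] <- p[1, ]; jj[[k]] <- p[2, ]
    }
    for (o in seq_len(nrow(offsets))) {
      nb <- occupied[c_idx, ] + offsets[o, ]
      if (any(nb < 0) || any(nb >= dims)) next
      other <- cell[[as.character(keyof(nb[1], nb[2], nb[3]))]]
      if (is.null(other)) next
      g <- expand.grid(a = home, b = other)
      k <- k + 1L
      ii[[k]] <- pmin(g$a, g$b); jj[[k]] <- pmax(g$a, g$b)
    }
  }
  if (k == 0L) return(cbind(i = integer(0), j = integer(0)))
  cbind(i = unlist(ii), j = unlist(jj))
}

#' Build the distance-window contact graph over sites
#'
#' Two sites are in contact when their Euclidean distance lies inside the
#' inclusive window \code{[d_lo, d_hi]} and, for sites in the same chain,
#' their sequence separation \code{|seq_index_i - seq_index_j|} is at least
#' \code{min_seq_sep} (inter-chain pairs are always eligible). A cell-list
#' spatial index prunes the pair search; its edge set is identical to an
#' exhaustive all-pairs comparison.
#'
#' @param sites an \code{"interaction_sites"} data.frame
#'   (\code{\link{select_sites}} or \code{\link{sites_from_coords}}).
#' @param window inclusive distance window \code{c(d_lo, d_hi)} in
#'   Angstrom; default \code{c(1, 7)}, the preferred range for
#'   higher-order residue interactions.
#' @param min_seq_sep minimum intra-chain separation in sequence positions;
#'   the default 1 admits every distinct residue pair including sequence
#'   neighbours.
#' @return object of class \code{"contact_graph"}: list with \code{sites},
#'   \code{edges} (data.frame \code{i}, \code{j}, \code{dist}, \code{span},
#'   with \code{i < j}, sorted), \code{window}, \code{min_seq_sep}.
#' @export
contact_graph <- function(sites, window = c(1, 7), min_seq_sep = 1L) {
  stopifnot(inherits(sites, "data.frame"))
  if (nrow(sites) < 2)
    stop("empty selection: need at least 2 sites to build a contact graph")
  window <- as.numeric(window)
  if (length(window) != 2 || !all(is.finite(window)) ||
      window[1] < 0 || window[1] >= window[2])
    stop("invalid window: need 0 <= d_lo < d_hi")
  min_seq_sep <- as.integer(min_seq_sep)
  if (min_seq_sep < 0) stop("min_seq_sep must be >= 0")

  xyz <- as.matrix(sites[, c("x", "y", "z")])
  cand <- .candidate_pairs(xyz, window[2])
  if (nrow(cand) > 0) {
    d <- .site_dist(xyz, cand[, "i"], cand[, "j"])
    same_chain <- sites$chain[cand[, "i"]] == sites$chain[cand[, "j"]]
    sep_ok <- !same_chain |
      abs(sites$seq_index[cand[, "i"]] - sites$seq_index[cand[, "j"]]) >= min_seq_sep
    keep <- d >= window[1] & d <= window[2] & sep_ok
    edges <- data.frame(i = cand[keep, "i"], j = cand[keep, "j"],
                        dist = d[keep],
                        span = ifelse(same_chain[keep], "intra-chain",
                                      "inter-chain"),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), dist = numeric(0),
                        span = character(0), stringsAsFactors = FALSE)
  }
  edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(sites = sites, edges = edges, window = window,
                 min_seq_sep = min_seq_sep),
            class = "contact_graph")
}

#' Classify a contact edge as intra- or inter-chain
#'
#' @param graph a \code{"contact_graph"}.
#' @param i,j site indices of an existing edge (either order).
#' @return \code{"intra-chain"} or \code{"inter-chain"}.
#' @export
classify_edge <- function(graph, i, j) {
  stopifnot(inherits(graph, "contact_graph"))
  a <- min(i, j); b <- max(i, j)
  hit <- graph$edges$i == a & graph$edges$j == b
  if (!any(hit)) stop("unknown edge: (", i, ", ", j, ")")
  graph$edges$span[which(hit)[1]]
}

# adjacency list (sorted integer neighbour vectors) of a contact graph
.adjacency <- function(graph) {
  n <- nrow(graph$sites)
  e <- graph$edges
  adj <- split(c(e$j, e$i), factor(c(e$i, e$j), levels = seq_len(n)))
  lapply(adj, function(v) sort(unique(v)))
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf(
    "<contact graph: %d sites, %d edges, window [%.2f, %.2f] A, min_seq_sep %d>\n",
    nrow(x$sites), nrow(x$edges), x$window[1], x$window[2], x$min_seq_sep))
  invisible(x)
}
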