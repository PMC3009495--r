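.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

# Resolve an anchor spec to a site row index. Accepted forms:
# "CHAIN:RESNO", "CHAIN:RESNO:ICODE", or a bare residue number (only
# unambiguous when the selection holds a single chain).
.resolve_anchor <- function(sites, key) {
  key <- as.character(key)
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    chains <- unique(sites$chain)
    if (length(chains) > 1)
      stop("anchor not found: '", key,
           "' is ambiguous; use CHAIN:RESNUM with multiple chains (",
           paste(chains, collapse = ", "), ")")
    parts <- c(chains, parts)
  }
  chain <- parts[1]
  resno <- suppressWarnings(as.integer(parts[2]))
  insert <- if (length(parts) >= 3) parts[3] else ""
  if (is.na(resno)) stop("anchor not found: cannot parse '", key, "'")
  hit <- which(sites$chain == chain & sites$resno == resno &
               sites$insert == insert)
  if (length(hit) == 0)
    stop("anchor not found: ", site_key(chain, resno, insert))
  hit[1]
}

#' Interactions containing a set of anchor residues
#'
#' Returns the order-k interactions (cliques) whose member set contains
#' every anchor residue -- the anchored query of the residue-specific
#' module: pairwise/triplet/quadruplet interactions around 1 up to k named
#' residues. Computed by neighbourhood-restricted search; the result is
#' identical to filtering the full enumeration for anchor membership.
#'
#' @param graph a \code{"contact_graph"}.
#' @param anchors character vector (1 to \code{order} entries) of residue
#'   keys \code{"CHAIN:RESNUM[:ICODE]"}; a bare number is accepted for
#'   single-chain selections.
#' @param order interaction order, 2, 3 or 4.
#' @return an \code{"interaction_set"} of the requested order.
#' @export
interactions_around <- function(graph, anchors, order) {
  stopifnot(inherits(graph, "contact_graph"))
  order <- as.integer(order)
  if (!order %in% 2:4) stop("order must be 2, 3 or 4")
  if (length(anchors) < 1 || length(anchors) > order)
    stop("need between 1 and order (", order, ") anchors, got ",
         length(anchors))
  a <- vapply(anchors, function(k) .resolve_anchor(graph$sites, k), integer(1))
  if (anyDuplicated(a)) stop("anchor residues must be distinct")
  a <- sort(unname(a))
  adj <- .adjacency(graph)

  # all anchors must be mutually in contact, else no clique contains them
  if (length(a) > 1) {
    for (p in seq_along(a)[-1])
      for (q in seq_len(p - 1))
        if (!a[p] %in% adj[[a[q]]])
          return(.new_interaction_set(matrix(integer(0), ncol = order),
                                      graph, order))
  }
  need <- order - length(a)
  cand <- sort(setdiff(Reduce(intersect, adj[a]), a))
  complete <- if (need == 0) {
    matrix(a, nrow = 1)
  } else if (need == 1) {
    if (length(cand) > 0) cbind(matrix(a, nrow = length(cand), ncol = length(a),
                                       byrow = TRUE), cand)
    else matrix(integer(0), ncol = order)
  } else {
    # need 2 or 3 extra members, mutually adjacent among the candidates
    rows <- list(); nr <- 0L
    if (length(cand) >= need) {
      ext <- utils::combn(cand, need)
      for (c_idx in seq_len(ncol(ext))) {
        grp <- ext[, c_idx]
        ok <- TRUE
        for (p in seq_along(grp)[-1])
          for (q in seq_len(p - 1))
            if (!grp[p] %in% adj[[grp[q]]]) { ok <- FALSE; break }
        if (ok) { nr <- nr + 1L; rows[[nr]] <- c(a, grp) }
      }
    }
    if (nr == 0L) matrix(integer(0), ncol = order)
    else do.call(rbind, rows)
  }
  if (nrow(complete) > 0) {
    complete <- t(apply(complete, 1, sort))
    o <- do.call(base::order,
                 lapply(seq_len(order), function(c_idx) complete[, c_idx]))
    complete <- complete[o, , drop = FALSE]
  }
  .new_interaction_set(complete, graph, order)
}

#' Interactions involving residues of given amino-acid types
#'
#' The residue-type query: order-k interactions whose members match a set
#' of amino-acid types, either any member (\code{mode = "any"}, the
#' default: e.g. all quadruplets mediated by cysteines) or all members
#' (\code{mode = "all"}). Equivalent to filtering the full enumeration by
#' the type predicate.
#'
#' @param graph a \code{"contact_graph"}.
#' @param aa_types character vector of 3-letter amino-acid codes.
#' @param order interaction order, 2, 3 or 4.
#' @param mode \code{"any"} (at least one member of a listed type) or
#'   \code{"all"} (every member of a listed type).
#' @return an \code{"interaction_set"} of the requested order.
#' @export
interactions_by_type <- function(graph, aa_types, order, mode = c("any", "all")) {
  stopifnot(inherits(graph, "contact_graph"))
  mode <- match.arg(mode)
  order <- as.integer(order)
  if (!order %in% 2:4) stop("order must be 2, 3 or 4")
  aa_types <- toupper(aa_types)
  bad <- setdiff(aa_types, .aa3)
  if (length(aa_types) == 0 || length(bad) > 0)
    stop("invalid amino-acid code(s): ",
         paste(if (length(bad)) bad else "(none given)", collapse = ", "),
         "; valid codes: ", paste(.aa3, collapse = ", "))
  full <- switch(as.character(order),
                 "2" = enumerate_pairs(graph),
                 "3" = enumerate_triplets(graph),
                 "4" = enumerate_quadruplets(graph))
  m <- .members(full)
  if (nrow(m) == 0) return(full)
  typed <- matrix(graph$sites$resid[m] %in% aa_types, nrow = nrow(m))
  keep <- if (mode == "any") rowSums(typed) > 0 else rowSums(typed) == order
  out <- full[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_set", "data.frame")
  attr(out, "order") <- attr(full, "order")
  attr(out, "sites") <- attr(full, "sites")
  attr(out, "window") <- attr(full, "window")
  attr(out, "min_seq_sep") <- attr(full, "min_seq_sep")
  out
}
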