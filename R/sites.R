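#' Site-selection policy
#'
#' Controls how one representative interaction point (site) is derived per
#' residue: which atom stands for the residue, how glycine (which lacks a
#' C-beta) is handled, which model/chains/residue range are used, and how
#' alternate locations are resolved.
#'
#' @param atom_type representative atom, \code{"CA"} or \code{"CB"}.
#' @param gly_policy when \code{atom_type = "CB"} and a residue lacks a
#'   C-beta (glycine, or truncated side-chain density):
#'   \code{"fallback_to_ca"} substitutes the C-alpha (the site is marked
#'   \code{source_atom = "CA-fallback"}), \code{"skip"} drops the residue.
#' @param model model number for multi-model (NMR) entries; default first.
#' @param chains optional character vector of chain ids to keep.
#' @param residue_range optional \code{c(start, end)} author residue
#'   numbers (inclusive).
#' @param include_hetero keep non-water heterogen residues (default FALSE;
#'   waters are excluded at parse time, MSE counts as MET).
#'
#' @details Alternate locations are resolved per (residue, atom name) by
#' highest occupancy, ties broken alphabetically by altloc id.
#'
#' @return an object of class \code{"site_policy"}.
#' @export
site_policy <- function(atom_type = c("CA", "CB"),
                        gly_policy = c("fallback_to_ca", "skip"),
                        model = 1L,
                        chains = NULL,
                        residue_range = NULL,
                        include_hetero = FALSE) {
  atom_type <- match.arg(atom_type)
  gly_policy <- match.arg(gly_policy)
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    if (residue_range[1] > residue_range[2])
      stop("residue_range start must be <= end")
  }
  structure(list(atom_type = atom_type, gly_policy = gly_policy,
                 model = as.integer(model), chains = chains,
                 residue_range = residue_range,
                 include_hetero = isTRUE(include_hetero)),
            class = "site_policy")
}

# canonical residue key string CHAIN:RESNO[:ICODE]
site_key <- function(chain, resno, insert) {
  paste0(chain, ":", resno, ifelse(insert == "", "", paste0(":", insert)))
}

#' Select per-residue interaction sites
#'
#' Reduces a structure to one site per residue: the coordinate of the
#' requested representative atom (C-alpha or C-beta) plus the residue's
#' identity. Alternate locations are resolved by highest occupancy (ties
#' alphabetical). Residues lacking the representative atom follow
#' \code{gly_policy}; residues lacking even a C-alpha are skipped with a
#' warning. \code{seq_index} is the residue's 0-based ordinal position
#' within its chain (over all residues that pass the hetero filter), so
#' sequence separation survives residue-range filtering.
#'
#' @param x an \code{structure3d}.
#' @param policy a \code{\link{site_policy}}.
#' @return data.frame of class \code{"interaction_sites"} with columns
#'   \code{chain}, \code{resno}, \code{insert}, \code{resid},
#'   \code{seq_index}, \code{x}, \code{y}, \code{z}, \code{source_atom},
#'   ordered by (chain, seq_index); attributes record the policy and the
#'   structure id.
#' @export
select_sites <- function(x, policy = site_policy()) {
  stopifnot(inherits(x, "structure3d"), inherits(policy, "site_policy"))
  a <- x$atoms[x$atoms$model == policy$model, , drop = FALSE]
  if (nrow(a) == 0)
    stop("model not found: ", policy$model, " (structure has ",
         n_models(x), " model(s))")
  if (!is.null(policy$chains)) {
    avail <- unique(a$chain)
    missing_ch <- setdiff(policy$chains, avail)
    if (length(missing_ch) > 0)
      stop("chain not found: ", paste(missing_ch, collapse = ", "),
           " (available: ", paste(avail, collapse = ", "), ")")
    a <- a[a$chain %in% policy$chains, , drop = FALSE]
  }
  if (!policy$include_hetero) a <- a[!a$het, , drop = FALSE]
  if (nrow(a) == 0) stop("empty selection: no residues after filtering")

  # residue table in file order; seq_index assigned per chain before any
  # residue-range or atom-availability filtering
  rkey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(rkey)
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resid = a$resid[first],
                    key = rkey[first], stringsAsFactors = FALSE)
  res$seq_index <- stats::ave(seq_len(nrow(res)), res$chain,
                              FUN = function(i) seq_along(i) - 1L)

  if (!is.null(policy$residue_range)) {
    res <- res[res$resno >= policy$residue_range[1] &
               res$resno <= policy$residue_range[2], , drop = FALSE]
  }
  if (nrow(res) == 0) stop("empty selection: no residues in range")

  pick_atom <- function(sub, elety) {
    cand <- sub[sub$elety == elety, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(-cand$occ, cand$alt), , drop = FALSE]
    cand[1, ]
  }

  out <- vector("list", nrow(res))
  dropped <- character(0)
  for (r in seq_len(nrow(res))) {
    sub <- a[rkey == res$key[r], , drop = FALSE]
    src <- policy$atom_type
    atom <- pick_atom(sub, policy$atom_type)
    if (is.null(atom) && policy$atom_type == "CB") {
      if (policy$gly_policy == "skip") next
      atom <- pick_atom(sub, "CA")
      src <- "CA-fallback"
    }
    if (is.null(atom)) {
      dropped <- c(dropped, site_key(res$chain[r], res$resno[r], res$insert[r]))
      next
    }
    out[[r]] <- data.frame(
      chain = res$chain[r], resno = res$resno[r], insert = res$insert[r],
      resid = res$resid[r], seq_index = res$seq_index[r],
      x = atom$x, y = atom$y, z = atom$z, source_atom = src,
      stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0)
    warning("skipped residue(s) lacking a representative atom: ",
            paste(dropped, collapse = ", "))
  sites <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(sites) || nrow(sites) == 0)
    stop("empty selection: no residue provides the requested atom")
  sites <- sites[order(sites$chain, sites$seq_index), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("interaction_sites", "data.frame")
  attr(sites, "structure_id") <- x$id
  attr(sites, "atom_type") <- policy$atom_type
  attr(sites, "model") <- policy$model
  sites
}

#' Build interaction sites directly from coordinates
#'
#' Convenience constructor for synthetic geometries and tests: each row of
#' \code{coords} becomes one residue's site, numbered sequentially within
#' its chain.
#'
#' @param coords numeric matrix (n x 3) of coordinates in Angstrom.
#' @param chain chain id, recycled to n rows.
#' @param resid 3-letter residue type, recycled.
#' @param resno author residue numbers; default 1..n within each chain.
#' @param id structure label stored on the result.
#' @return an \code{"interaction_sites"} data.frame.
#' @export
sites_from_coords <- function(coords, chain = "A", resid = "ALA",
                              resno = NULL, id = "coords") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  n <- nrow(coords)
  chain <- rep_len(chain, n)
  resid <- rep_len(resid, n)
  seq_index <- stats::ave(seq_len(n), chain, FUN = function(i) seq_along(i) - 1L)
  if (is.null(resno)) resno <- seq_index + 1L
  sites <- data.frame(chain = chain, resno = as.integer(resno),
                      insert = "", resid = resid, seq_index = seq_index,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      source_atom = "CA", stringsAsFactors = FALSE)
  sites <- sites[order(sites$chain, sites$seq_index), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("interaction_sites", "data.frame")
  attr(sites, "structure_id") <- id
  attr(sites, "atom_type") <- "CA"
  attr(sites, "model") <- 1L
  sites
}

#' @export
print.interaction_sites <- function(x, ...) {
  cat(sprintf("<%d interaction sites (%s) from '%s', %d chain(s)>\n",
              nrow(x), attr(x, "atom_type"), attr(x, "structure_id"),
              length(unique(x$chain))))
  NextMethod()
}
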