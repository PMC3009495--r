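# ---- synthetic structure generators -------------------------------------
#
# These generators produce structures with known, closed-form geometry so
# every enumeration code path can be exercised without downloading real
# coordinates. They emit full structure3d objects (CA + CB atoms) and are
# PDB-round-trippable.

# assemble a structure3d from per-residue CA (and optional CB) coordinates
.structure_from_trace <- function(id, ca, cb = NULL, chain = "A",
                                  sequence = NULL, resno = NULL) {
  n <- nrow(ca)
  chain <- rep_len(chain, n)
  if (is.null(sequence)) sequence <- rep("ALA", n)
  sequence <- rep_len(sequence, n)
  if (is.null(resno))
    resno <- as.integer(stats::ave(seq_len(n), chain, FUN = seq_along))
  rows <- list(data.frame(
    model = 1L, chain = chain, resno = resno, insert = "",
    resid = sequence, elety = "CA", alt = "", occ = 1,
    x = ca[, 1], y = ca[, 2], z = ca[, 3], het = FALSE,
    stringsAsFactors = FALSE))
  if (!is.null(cb)) {
    keep <- sequence != "GLY"   # glycine has no C-beta
    rows[[2]] <- data.frame(
      model = 1L, chain = chain[keep], resno = resno[keep], insert = "",
      resid = sequence[keep], elety = "CB", alt = "", occ = 1,
      x = cb[keep, 1], y = cb[keep, 2], z = cb[keep, 3], het = FALSE,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  # interleave by residue so the file reads naturally
  atoms <- atoms[order(atoms$chain, atoms$resno,
                       match(atoms$elety, c("CA", "CB"))), ]
  new_structure(id, atoms)
}

#' Generate an ideal alpha-helix
#'
#' C-alpha trace on the canonical alpha-helix: radius 2.3 A, rise 1.5 A
#' per residue, 100 degree twist per residue, so consecutive C-alphas are
#' ~3.8 A apart and the i, i+4 distance is ~6.2 A. C-beta atoms are placed
#' 1.53 A from the C-alpha along the outward helix normal (except
#' glycine).
#'
#' @param n_residues number of residues (>= 2).
#' @param sequence optional 3-letter codes, recycled (default poly-ALA).
#' @param chain chain id.
#' @param radius,rise,twist helix parameters (A, A/residue, degrees/residue).
#' @return a \code{"structure3d"}.
#' @export
generate_ideal_helix <- function(n_residues, sequence = NULL, chain = "A",
                                 radius = 2.3, rise = 1.5, twist = 100) {
  if (n_residues < 2) stop("need at least 2 residues")
  i <- seq_len(n_residues) - 1
  theta <- i * twist * pi / 180
  ca <- cbind(radius * cos(theta), radius * sin(theta), rise * i)
  cb <- ca + 1.53 * cbind(cos(theta), sin(theta), 0)
  .structure_from_trace(sprintf("helix_n%d", n_residues), ca, cb,
                        chain = chain, sequence = sequence)
}

#' Closed-form C-alpha distance on the ideal helix
#'
#' Distance between residues i and i+k on the canonical helix:
#' \code{sqrt((2 r sin(k * twist/2))^2 + (k * rise)^2)}.
#'
#' @param k sequence offset.
#' @param radius,rise,twist helix parameters as in
#'   \code{\link{generate_ideal_helix}}.
#' @return distance in Angstrom.
#' @export
helix_ca_distance <- function(k, radius = 2.3, rise = 1.5, twist = 100) {
  chord <- 2 * radius * abs(sin(k * twist * pi / 360))
  sqrt(chord^2 + (k * rise)^2)
}

#' Generate a random packing of residues in a box
#'
#' Places \code{n_residues} C-alpha positions uniformly in a cubic box,
#' rejection-sampled so that every pair is at least \code{min_separation}
#' apart; reproducible from \code{seed}. C-beta atoms sit 1.53 A from each
#' C-alpha along a fixed offset direction. Sampling is bounded at 10,000
#' retries per site and fails deterministically when the packing is
#' infeasible.
#'
#' @param n_residues number of residues (>= 2).
#' @param seed integer RNG seed.
#' @param box_edge box edge length in Angstrom.
#' @param min_separation minimum pairwise distance in Angstrom
#'   (0 < min_separation < box_edge).
#' @param sequence optional 3-letter codes, recycled (default poly-ALA).
#' @param chain chain id(s), recycled over residues (several ids give a
#'   multi-chain structure).
#' @param max_retries rejection-sampling bound per site.
#' @return a \code{"structure3d"}.
#' @export
generate_random_packing <- function(n_residues, seed, box_edge = 30,
                                    min_separation = 3, sequence = NULL,
                                    chain = "A", max_retries = 10000L) {
  if (n_residues < 2) stop("need at least 2 residues")
  if (min_separation <= 0 || min_separation >= box_edge)
    stop("need 0 < min_separation < box_edge")
  # keep the caller's RNG state untouched
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  pts <- matrix(NA_real_, n_residues, 3)
  for (s in seq_len(n_residues)) {
    placed <- FALSE
    for (try_i in seq_len(max_retries)) {
      p <- stats::runif(3, 0, box_edge)
      if (s == 1 ||
          min(.site_dist(rbind(pts[seq_len(s - 1), , drop = FALSE], p),
                         seq_len(s - 1), s)) >= min_separation) {
        pts[s, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("packing infeasible after ", max_retries,
           " retries at site ", s, "; increase box_edge or lower ",
           "min_separation")
  }
  cb <- pts + 1.53 / sqrt(3)
  .structure_from_trace(sprintf("packing_n%d_seed%d", n_residues, seed),
                        pts, cb, chain = chain, sequence = sequence)
}

#' Generate a regular polyhedron / polygon of residues
#'
#' Small exact geometries used throughout the tests: the regular
#' tetrahedron is the canonical mutual-contact quadruplet (complete graph
#' K4); the square's diagonal exceeds its side by sqrt(2), so at
#' edge-length windows it yields a 4-cycle with no 4-clique.
#'
#' @param shape \code{"tetrahedron"}, \code{"square"} or
#'   \code{"octahedron"}.
#' @param edge edge length in Angstrom (default 5).
#' @param chain chain id.
#' @param sequence optional 3-letter codes, recycled.
#' @return a \code{"structure3d"} (C-alpha only).
#' @export
generate_polyhedron <- function(shape = c("tetrahedron", "square",
                                          "octahedron"),
                                edge = 5, chain = "A", sequence = NULL) {
  shape <- match.arg(shape)
  ca <- switch(shape,
    tetrahedron = edge / (2 * sqrt(2)) *
      rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    square = edge *
      rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    octahedron = edge / sqrt(2) *
      rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  .structure_from_trace(paste0(shape, "_e", edge), ca, cb = NULL,
                        chain = chain, sequence = sequence)
}

# ---- brute-force oracle --------------------------------------------------

# combn(n, k) is re-used across many oracle runs; cache the index matrices
.combn_cache <- new.env(parent = emptyenv())
.combn_cached <- function(n, k) {
  key <- paste(n, k, sep = ":")
  if (is.null(.combn_cache[[key]]))
    .combn_cache[[key]] <- utils::combn(n, k)
  .combn_cache[[key]]
}

#' Brute-force clique enumeration (testing oracle)
#'
#' Exhaustively scans every order-sized subset of sites and keeps those
#' whose pairwise distances all lie in the window and whose intra-chain
#' pairs respect the minimum sequence separation -- a literal restatement
#' of the mutual-contact definition, independent of the cell-list and
#' clique-extension code paths. Intended for validation on small inputs
#' only (guard: n <= 100).
#'
#' @param sites an \code{"interaction_sites"} data.frame.
#' @param order 2, 3 or 4.
#' @param window inclusive distance window \code{c(d_lo, d_hi)}.
#' @param min_seq_sep minimum intra-chain sequence separation.
#' @return an \code{"interaction_set"} in the same canonical order as the
#'   main enumeration.
#' @export
brute_force_cliques <- function(sites, order, window = c(1, 7),
                                min_seq_sep = 1L) {
  n <- nrow(sites)
  if (n > 100) stop("brute-force oracle is guarded at n <= 100 (got ", n, ")")
  order <- as.integer(order)
  stopifnot(order %in% 2:4)
  # independent distance path: stats::dist over all pairs
  dm <- as.matrix(stats::dist(as.matrix(sites[, c("x", "y", "z")])))
  subsets <- .combn_cached(n, order)
  pair_idx <- utils::combn(order, 2)
  keep <- rep(TRUE, ncol(subsets))
  for (p in seq_len(ncol(pair_idx))) {
    a <- subsets[pair_idx[1, p], ]
    b <- subsets[pair_idx[2, p], ]
    d <- dm[cbind(a, b)]
    ok <- d >= window[1] & d <= window[2] &
      (sites$chain[a] != sites$chain[b] |
         abs(sites$seq_index[a] - sites$seq_index[b]) >= min_seq_sep)
    keep <- keep & ok
  }
  members <- t(subsets[, keep, drop = FALSE])
  graph_like <- list(sites = sites, window = as.numeric(window),
                     min_seq_sep = as.integer(min_seq_sep))
  .new_interaction_set(members, graph_like, order)
}
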