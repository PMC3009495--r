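#' Whole-structure higher-order interaction run
#'
#' Convenience pipeline mirroring a full enumeration run: select sites
#' under a policy, build the contact graph, enumerate interactions at the
#' requested orders, and summarize. Equivalent to calling
#' \code{\link{select_sites}}, \code{\link{contact_graph}},
#' \code{\link{enumerate_interactions}} and
#' \code{\link{summarize_interactions}} in sequence.
#'
#' @param x a \code{"structure3d"} (or path to a PDB file).
#' @param atom_type representative atom, \code{"CA"} or \code{"CB"}.
#' @param window inclusive distance window in Angstrom (default
#'   \code{c(1, 7)}).
#' @param orders integer subset of \code{c(2, 3, 4)}.
#' @param min_seq_sep minimum intra-chain sequence separation (default 1).
#' @param chains,residue_range,model,gly_policy passed to
#'   \code{\link{site_policy}}.
#' @return object of class \code{"hoi_run"}: list with \code{sites},
#'   \code{graph}, \code{interactions} (named list of interaction sets)
#'   and \code{summary}.
#' @examples
#' s <- generate_ideal_helix(18)
#' run <- hoi_run(s, atom_type = "CA", window = c(1, 7))
#' run$summary$counts
#' @export
hoi_run <- function(x, atom_type = c("CA", "CB"), window = c(1, 7),
                    orders = c(2, 3, 4), min_seq_sep = 1L,
                    chains = NULL, residue_range = NULL, model = 1L,
                    gly_policy = "fallback_to_ca") {
  if (is.character(x)) x <- read_structure(x)
  atom_type <- match.arg(atom_type)
  policy <- site_policy(atom_type = atom_type, gly_policy = gly_policy,
                        model = model, chains = chains,
                        residue_range = residue_range)
  sites <- select_sites(x, policy)
  graph <- contact_graph(sites, window = window, min_seq_sep = min_seq_sep)
  ints <- enumerate_interactions(graph, orders = orders)
  structure(list(sites = sites, graph = graph, interactions = ints,
                 summary = summarize_interactions(ints, sites)),
            class = "hoi_run")
}

#' @export
print.hoi_run <- function(x, ...) {
  print(x$graph)
  print(x$summary)
  invisible(x)
}
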