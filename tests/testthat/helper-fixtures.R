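# Shared builders for the suite. All fixtures are constructed in code.

# minimal hand-written PDB text: ALA 1 (N, CA, CB), GLY 2 (CA)
minimal_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1      12.919   6.898  -5.041  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       8.444   6.221  -4.915  1.00  0.00           C")
}

# same content duplicated into two NMR-style models
two_model_pdb_lines <- function() {
  body <- minimal_pdb_lines()
  c("MODEL        1", body, "ENDMDL", "MODEL        2", body, "ENDMDL", "END")
}

# one CA with two alternate locations: A at occupancy 0.4, B at 0.6
altloc_pdb_lines <- function() {
  c("ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       5.000   0.000   0.000  1.00  0.00           C")
}

# graph helper for raw coordinate geometry
graph_of <- function(coords, window = c(1, 7), min_seq_sep = 1,
                     chain = "A", resid = "ALA") {
  contact_graph(sites_from_coords(coords, chain = chain, resid = resid),
                window = window, min_seq_sep = min_seq_sep)
}

# frozen member-key tuples for set comparisons between engine and oracle
member_keys <- function(x) sort(resclique:::.member_keys(x))

# order-free tuple keys: members sorted lexicographically within each
# tuple, rows sorted -- robust to site relabeling/permutation
tuple_set_keys <- function(x) {
  sites <- attr(x, "sites")
  m <- resclique:::.members(x)
  if (nrow(m) == 0) return(character(0))
  keys <- matrix(site_key(sites$chain[m], sites$resno[m], sites$insert[m]),
                 nrow = nrow(m))
  sort(apply(keys, 1, function(r) paste(sort(r), collapse = "|")))
}

# engine/oracle agreement check at one order
expect_oracle_equal <- function(sites, order, window, min_seq_sep = 1) {
  g <- contact_graph(sites, window = window, min_seq_sep = min_seq_sep)
  eng <- switch(as.character(order),
                "2" = enumerate_pairs(g),
                "3" = enumerate_triplets(g),
                "4" = enumerate_quadruplets(g))
  ora <- brute_force_cliques(sites, order, window = window,
                             min_seq_sep = min_seq_sep)
  expect_identical(member_keys(eng), member_keys(ora))
  # distances must agree too (different arithmetic paths, so tolerance)
  dcols <- grep("^d[0-9]{2}$", names(eng), value = TRUE)
  for (cc in dcols)
    expect_equal(sort(eng[[cc]]), sort(ora[[cc]]), tolerance = 1e-9)
  invisible(list(engine = eng, oracle = ora))
}
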