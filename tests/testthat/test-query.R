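test_that("anchored query on the tetrahedron returns its one quadruplet", {
  tet <- generate_polyhedron("tetrahedron", edge = 5)
  g <- contact_graph(select_sites(tet, site_policy("CA")), c(1, 7))
  r <- interactions_around(g, "A:1", 4)
  expect_equal(nrow(r), 1)
  expect_equal(unlist(r[1, c("m1", "m2", "m3", "m4")], use.names = FALSE),
               1:4)
  # all four anchors: the single candidate tuple
  r4 <- interactions_around(g, c("A:1", "A:2", "A:3", "A:4"), 4)
  expect_equal(nrow(r4), 1)
})

test_that("anchored queries equal full enumeration filtered for membership", {
  for (seed in c(5, 23)) {
    s <- generate_random_packing(40, seed = seed, box_edge = 24,
                                 chain = c("A", "B"))
    sites <- select_sites(s, site_policy("CA"))
    g <- contact_graph(sites, c(1, 7))
    full <- enumerate_interactions(g)
    for (order in 2:4) {
      fm <- resclique:::.members(full[[order - 1]])
      fkeys <- resclique:::.member_keys(full[[order - 1]])
      # single anchor: every site that joins at least one clique, plus one
      # that joins none
      probe <- setdiff(seq_len(nrow(sites)), as.vector(fm))[1]
      if (nrow(fm) > 0) probe <- c(as.vector(fm[1, ]), probe)
      probe <- unique(probe[!is.na(probe)])
      for (idx in probe) {
        key <- site_key(sites$chain[idx], sites$resno[idx], sites$insert[idx])
        got <- member_keys(interactions_around(g, key, order))
        want <- sort(fkeys[apply(fm == idx, 1, any)])
        expect_identical(got, want)
      }
      # two anchors from the first clique, when the order admits them
      if (nrow(fm) > 0 && order >= 3) {
        pairkeys <- site_key(sites$chain[fm[1, 1:2]], sites$resno[fm[1, 1:2]],
                             sites$insert[fm[1, 1:2]])
        got <- member_keys(interactions_around(g, pairkeys, order))
        want <- sort(fkeys[apply(fm == fm[1, 1], 1, any) &
                           apply(fm == fm[1, 2], 1, any)])
        expect_identical(got, want)
      }
    }
  }
})

test_that("adding an anchor never enlarges the result", {
  s <- generate_random_packing(50, seed = 47, box_edge = 26)
  sites <- select_sites(s, site_policy("CA"))
  g <- contact_graph(sites, c(1, 7))
  tri <- enumerate_triplets(g)
  m <- resclique:::.members(tri)
  expect_gt(nrow(m), 0)
  k1 <- site_key(sites$chain[m[1, 1]], sites$resno[m[1, 1]], sites$insert[m[1, 1]])
  k2 <- site_key(sites$chain[m[1, 2]], sites$resno[m[1, 2]], sites$insert[m[1, 2]])
  one <- member_keys(interactions_around(g, k1, 3))
  two <- member_keys(interactions_around(g, c(k1, k2), 3))
  expect_true(all(two %in% one))
  expect_true(all(one %in% member_keys(tri)))
})

test_that("anchor errors: unknown key, too many anchors, ambiguity", {
  s <- generate_random_packing(10, seed = 3, chain = c("A", "B"))
  g <- contact_graph(select_sites(s, site_policy("CA")), c(1, 7))
  expect_error(interactions_around(g, "A:999", 3), "anchor not found: A:999")
  expect_error(interactions_around(g, c("A:1", "A:2", "A:3"), 2),
               "between 1 and order")
  expect_error(interactions_around(g, "4", 2), "ambiguous")
  # bare numbers are fine on single-chain selections
  s1 <- generate_random_packing(10, seed = 3)
  g1 <- contact_graph(select_sites(s1, site_policy("CA")), c(1, 7))
  expect_s3_class(interactions_around(g1, "4", 2), "interaction_set")
})

test_that("type queries filter the full enumeration by residue type", {
  s <- generate_random_packing(45, seed = 53, box_edge = 25,
                               sequence = c("ALA", "CYS", "HIS"))
  sites <- select_sites(s, site_policy("CA"))
  g <- contact_graph(sites, c(1, 7))
  for (order in 2:3) {
    full <- switch(order - 1, enumerate_pairs(g), enumerate_triplets(g))
    m <- resclique:::.members(full)
    typed <- matrix(sites$resid[m] %in% "CYS", nrow = nrow(m))
    any_want <- sort(resclique:::.member_keys(full)[rowSums(typed) > 0])
    any_got <- member_keys(interactions_by_type(g, "CYS", order, "any"))
    expect_identical(any_got, any_want)
    all_want <- sort(resclique:::.member_keys(full)[rowSums(typed) == order])
    all_got <- member_keys(interactions_by_type(g, "CYS", order, "all"))
    expect_identical(all_got, all_want)
    expect_true(all(all_got %in% any_got))
  }
})

test_that("every cysteine-typed quadruplet contains a cysteine", {
  s <- generate_random_packing(60, seed = 59, box_edge = 26,
                               sequence = c("ALA", "ALA", "CYS"))
  sites <- select_sites(s, site_policy("CA"))
  g <- contact_graph(sites, c(1, 7))
  q <- interactions_by_type(g, "CYS", 4, "any")
  m <- resclique:::.members(q)
  if (nrow(m) > 0) {
    has_cys <- apply(matrix(sites$resid[m] == "CYS", nrow = nrow(m)), 1, any)
    expect_true(all(has_cys))
  }
  # a structure with no cysteine yields an empty result at every order
  s0 <- generate_random_packing(20, seed = 1)
  g0 <- contact_graph(select_sites(s0, site_policy("CA")), c(1, 7))
  for (order in 2:4)
    expect_equal(nrow(interactions_by_type(g0, "CYS", order)), 0)
})

test_that("invalid amino-acid codes are rejected with the valid list", {
  s <- generate_random_packing(10, seed = 3)
  g <- contact_graph(select_sites(s, site_policy("CA")), c(1, 7))
  expect_error(interactions_by_type(g, "XXX", 2), "invalid amino-acid")
  expect_error(interactions_by_type(g, "XXX", 2), "ALA")
})
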