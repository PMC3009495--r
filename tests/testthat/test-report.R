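test_that("a single pair writes one data row with a 2-decimal distance", {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  sites <- sites_from_coords(coords, resid = c("ALA", "GLY"))
  g <- contact_graph(sites, c(1, 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions_tsv(enumerate_pairs(g), f)
  lines <- readLines(f)
  prov <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  expect_true(any(grepl("window", prov)))
  expect_equal(length(body), 2)             # header + 1 row
  row <- strsplit(body[2], "\t")[[1]]
  expect_equal(row[1], "2")
  expect_equal(row[2], "A:ALA:1")
  expect_equal(row[3], "A:GLY:2")
  expect_equal(row[4], "3.80")
  expect_equal(row[5], "intra-chain")
})

test_that("an empty interaction list writes provenance and header only", {
  g <- graph_of(rbind(c(0, 0, 0), c(100, 0, 0)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions_tsv(enumerate_pairs(g), f)
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, "#")), 1)
})

test_that("a quadruplet row carries 4 member fields and 6 distances", {
  tet <- generate_polyhedron("tetrahedron", edge = 5)
  g <- contact_graph(select_sites(tet, site_policy("CA")), c(1, 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions_tsv(enumerate_quadruplets(g), f)
  body <- readLines(f)
  body <- body[!startsWith(body, "#")]
  row <- strsplit(body[2], "\t")[[1]]
  header <- strsplit(body[1], "\t")[[1]]
  expect_equal(sum(grepl("^member", header)), 4)
  expect_equal(sum(grepl("^d[0-9]{2}$", header)), 6)
  expect_equal(row[grepl("^d", header)], rep("5.00", 6))
})

test_that("written tables round-trip exactly at reporting precision", {
  s <- generate_random_packing(40, seed = 61, box_edge = 24,
                               chain = c("A", "B"),
                               sequence = c("ALA", "CYS", "GLY"))
  sites <- select_sites(s, site_policy("CB"))
  g <- contact_graph(sites, c(1, 7))
  res <- enumerate_interactions(g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions_tsv(res, f)
  back <- read_interactions_tsv(f)
  expect_equal(nrow(back), sum(vapply(res, nrow, integer(1))))
  # pairs: order, members, distance and span survive
  p <- back[back$order == 2, ]
  want <- format_interactions(res$pairs)
  expect_equal(p$member1, want$member1)
  expect_equal(p$member2, want$member2)
  expect_equal(p$d12, as.numeric(want$d12))
  expect_equal(p$span, want$span)
  q <- back[back$order == 4, ]
  wantq <- format_interactions(res$quadruplets)
  expect_equal(q$member4, wantq$member4)
  expect_equal(q$d34, as.numeric(wantq$d34))
})

test_that("identical inputs produce byte-identical outputs", {
  s <- generate_random_packing(50, seed = 67, box_edge = 26)
  sites <- select_sites(s, site_policy("CA"))
  g <- contact_graph(sites, c(1, 7))
  res <- enumerate_interactions(g)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_interactions_tsv(res, f1)
  write_interactions_tsv(enumerate_interactions(contact_graph(sites, c(1, 7))), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("both visualization dialects select identical residue sets", {
  s <- generate_random_packing(30, seed = 71, box_edge = 20,
                               chain = c("A", "B"))
  sites <- select_sites(s, site_policy("CA"))
  g <- contact_graph(sites, c(1, 7))
  tri <- enumerate_triplets(g)
  expect_gt(nrow(tri), 0)
  f_ras <- withr::local_tempfile(fileext = ".spt")
  f_jmol <- withr::local_tempfile(fileext = ".spt")
  write_viz_script(tri, "rasmol", f_ras)
  write_viz_script(tri, "jmol", f_jmol)
  sel_of <- function(lines) {
    sel <- grep("^select ", lines, value = TRUE)
    sel <- sel[!grepl("select all", sel)]
    lapply(strsplit(sub(";.*$", "", sub("^select ", "", sel)), ",\\s*"),
           sort)
  }
  expect_identical(sel_of(readLines(f_ras)), sel_of(readLines(f_jmol)))
  # residue numbers restricted to the right chain
  m <- resclique:::.members(tri)
  tok <- paste0(sites$resno[m[1, 1]], ":", sites$chain[m[1, 1]])
  expect_true(any(grepl(tok, readLines(f_ras), fixed = TRUE)))
  expect_error(write_viz_script(tri, "pymol", withr::local_tempfile()))
})

test_that("summaries count the complete graph K4 and satisfy participation", {
  tet <- generate_polyhedron("tetrahedron", edge = 5)
  g <- contact_graph(select_sites(tet, site_policy("CA")), c(1, 7))
  res <- enumerate_interactions(g)
  sm <- summarize_interactions(res)
  expect_equal(sm$counts$n, c(6, 4, 1))
  # every vertex of K4 joins 3 pairs, 3 triplets, 1 quadruplet
  expect_equal(sm$participation$order2, rep(3, 4))
  expect_equal(sm$participation$order3, rep(3, 4))
  expect_equal(sm$participation$order4, rep(1, 4))
})

test_that("participation totals equal order times interaction count", {
  s <- generate_random_packing(60, seed = 73, box_edge = 26)
  sites <- select_sites(s, site_policy("CA"))
  res <- enumerate_interactions(contact_graph(sites, c(1, 7)))
  sm <- summarize_interactions(res, sites)
  for (k in 2:4)
    expect_equal(sum(sm$participation[[paste0("order", k)]]),
                 k * sm$counts$n[sm$counts$order == k])
  # empty graph: all-zero summary
  far <- graph_of(rbind(c(0, 0, 0), c(500, 0, 0)))
  sm0 <- summarize_interactions(enumerate_interactions(far))
  expect_true(all(sm0$counts$n == 0))
})
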