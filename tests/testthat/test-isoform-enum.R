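zm9_edges_df <- function() {
  data.frame(edge_id = c("common", "alt_large", "alt_small"),
             from = c("n1", "n2", "n2"),
             to = c("n2", "n1", "n1"),
             length = c(149304L, 35405L, 2339L),
             stringsAsFactors = FALSE)
}

## Rep copies placed at the fixture coordinates within each edge:
## common = a(30000) b(3695) c(20000) d(4845) e(70665) b(3695) f(16404),
## alt_large = g(12000) d(4845) h(18560).
zm9_repeat_copies <- function() {
  data.frame(
    edge_id = c("common", "common", "common", "alt_large"),
    start = c(30000L, 30000L + 3695L + 20000L,
              30000L + 3695L + 20000L + 4845L + 70665L, 12000L),
    end = c(30000L + 3695L, 30000L + 3695L + 20000L + 4845L,
            30000L + 3695L + 20000L + 4845L + 70665L + 3695L,
            12000L + 4845L),
    repeat_name = c("Rep2", "Rep1", "Rep2", "Rep1"),
    stringsAsFactors = FALSE)
}

test_that("cutting the three-edge graph at repeat copies yields the nine-segment architecture", {
  sg <- segment_genome(zm9_edges_df(), zm9_repeat_copies(),
                       piece_labels = letters[1:9])
  expect_equal(nrow(sg$graph$segments), 9L)
  expect_equal(nrow(sg$graph$junctions), 12L)
  fx <- zm9_fixture()
  expect_setequal(sg$graph$junctions$key, fx$graph$junctions$key)
  expect_equal(sg$graph$repeat_copies[c("b", "d")], c(b = 2L, d = 2L))
  ## segment lengths match the fixture
  expect_equal(sg$graph$segments$length[match(letters[1:9],
                                              sg$graph$segments$id)],
               unname(fx$graph$segments$length))
})

test_that("a single circular edge with no repeats is one self-adjacent segment", {
  edges <- data.frame(edge_id = "e1", from = "n", to = "n", length = 5000L)
  sg <- segment_genome(edges)
  expect_equal(nrow(sg$graph$segments), 1L)
  expect_equal(nrow(sg$graph$junctions), 1L)
  id <- sg$graph$segments$id
  expect_equal(sg$graph$junctions$key, canonical_junction(paste0(id, "+"),
                                                          paste0(id, "+")))
})

test_that("overlapping repeat copies are rejected", {
  edges <- data.frame(edge_id = "e1", from = "a", to = "b", length = 1000L)
  rc <- data.frame(edge_id = "e1", start = c(100L, 150L),
                   end = c(300L, 400L), repeat_name = c("R1", "R2"))
  expect_error(segment_genome(edges, rc), "overlap")
})

test_that("enumeration recovers the eight fixture isoforms exactly", {
  fx <- zm9_fixture()
  enum <- enumerate_isoforms(fx$graph)
  expect_length(enum, 8L)
  expect_identical(enum_signatures(enum), enum_signatures(fx$isoforms))
  cls <- classify_isoforms(enum, fx$graph)
  expect_length(cls$masters, 3L)
  expect_length(cls$subgenomes, 5L)
})

test_that("toy one-repeat circle has a master and two subcircles", {
  g <- toy_rxry_graph()
  enum <- enumerate_isoforms(g)
  expect_length(enum, 3L)
  cls <- classify_isoforms(enum, g)
  expect_length(cls$masters, 1L)
  expect_length(cls$subgenomes, 2L)
  rn <- reaction_network(enum, g)
  expect_equal(nrow(rn), 1L)
  expect_true(rn$in_pool)
  expect_equal(rn$repeat_id, "R")
})

test_that("a repeat-free circle is a single subgenome with no reactions", {
  segs <- segment_table(c("x", "y", "z"), c(10L, 20L, 30L))
  g <- build_segment_graph(segs, c("x>y", "y>z", "z>x"))
  enum <- enumerate_isoforms(g)
  expect_length(enum, 1L)
  cls <- classify_isoforms(enum, g)
  expect_length(cls$masters, 0L)
  expect_length(cls$subgenomes, 1L)
  expect_equal(nrow(reaction_network(enum, g)), 0L)
  ## an acyclic graph carries no isoform at all
  g2 <- build_segment_graph(segs, c("x>y", "y>z"))
  expect_length(enumerate_isoforms(g2), 0L)
})

test_that("the fixture reaction network matches the recombination chemistry", {
  fx <- zm9_fixture()
  rn <- reaction_network(fx$isoforms, fx$graph)
  expect_true(all(rn$in_pool))
  ## iso2 splits via Rep2 into isoI + isoII
  iso2 <- rn[rn$master == "iso2", ]
  expect_equal(nrow(iso2), 1L)
  expect_equal(iso2$repeat_name, "Rep2")
  expect_setequal(c(iso2$product1, iso2$product2), c("isoI", "isoII"))
  ## iso1 splits two ways: {isoI, isoV} via Rep2 and {isoIII, isoIV} via Rep1
  iso1 <- rn[rn$master == "iso1", ]
  expect_equal(nrow(iso1), 2L)
  prods <- lapply(seq_len(2), function(i)
    sort(c(iso1$product1[i], iso1$product2[i])))
  expect_setequal(lapply(prods, paste, collapse = "+"),
                  c("isoI+isoV", "isoIII+isoIV"))
})

test_that("reaction closure from the two major isoforms reaches exactly the eight", {
  fx <- zm9_fixture()
  closure <- reaction_closure(fx$isoforms[c("iso1", "iso2")], fx$graph)
  expect_identical(enum_signatures(closure), enum_signatures(fx$isoforms))
})

test_that("fission conserves junctions and segment instances", {
  set.seed(31)
  checked <- 0L
  for (rep_i in 1:30) {
    g <- random_graph()
    ## mark a random segment as repeat so masters can exist
    enum <- tryCatch(enumerate_isoforms(g), error = function(e) NULL)
    if (is.null(enum) || length(enum) == 0L) next
    for (iso in enum) {
      ids <- mitoforms:::os_id(iso$walk)
      dup <- unique(ids[duplicated(ids)])
      for (rid in dup) {
        occ <- which(ids == rid)
        for (a in seq_len(length(occ) - 1L)) for (b in (a + 1L):length(occ)) {
          if (substring(iso$walk[occ[a]], nchar(iso$walk[occ[a]])) !=
              substring(iso$walk[occ[b]], nchar(iso$walk[occ[b]]))) next
          pr <- mitoforms:::fission_products(iso$walk, occ[a], occ[b])
          ## segment instances conserved
          expect_equal(sort(c(pr[[1]], pr[[2]])), sort(iso$walk))
          ## junctions of products are a subset of the parent's
          parent_j <- isoform_junctions(iso)
          for (p in pr) {
            pj <- canonical_junction(p, c(p[-1], p[1]))
            expect_true(all(pj %in% parent_j))
          }
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 5L)
})

test_that("enumeration matches the exhaustive subset oracle on random multigraphs", {
  set.seed(101)
  n_graphs <- 100L
  for (i in seq_len(n_graphs)) {
    g <- random_graph()
    got <- enum_signatures(enumerate_isoforms(g))
    want <- oracle_enumerate_signatures(g)
    expect_identical(got, want)
  }
  ## and on the full twelve-junction fixture
  fx <- zm9_fixture()
  expect_identical(enum_signatures(enumerate_isoforms(fx$graph)),
                   oracle_enumerate_signatures(fx$graph))
})
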