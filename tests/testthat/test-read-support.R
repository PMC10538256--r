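## One synthetic genome shared by the read-support tests (built once).
rs_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- synth_genome(zm9_fixture(), seed = 7)
    g
  }
})

rs_index <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) idx <<- genome_read_index(rs_genome())
    idx
  }
})

## Extract [start, end) from an isoform sequence, wrapping circularly.
iso_substr <- function(genome, iso, start0, len) {
  s <- genome$isoform_seqs[[iso]]
  dbl <- paste0(s, s)
  substr(dbl, start0 + 1L, start0 + len)
}

test_that("reads project onto the segment paths they were sampled from", {
  genome <- rs_genome()
  idx <- rs_index()
  lay <- genome$layouts[["iso1"]]
  ## read across junction b -> c with 600 bp on each side
  p_bc <- lay$end[2L]   # boundary after the first b in iso1 = a,b,c,...
  rd <- iso_substr(genome, "iso1", p_bc - 600L, 1200L)
  rp <- read_to_segment_path(rd, genome, index = idx)
  expect_equal(rp$path, c("b+", "c+"))
  ## read wholly inside segment e
  e_row <- which(lay$segment == "e")
  rd2 <- iso_substr(genome, "iso1", lay$start[e_row] + 1000L, 5000L)
  rp2 <- read_to_segment_path(rd2, genome, index = idx)
  expect_equal(rp2$path, "e+")
  ## read along iso1* spanning g, d, e
  lay_star <- genome$layouts[["iso1*"]]
  g_row <- which(lay_star$segment == "g")
  rd3 <- iso_substr(genome, "iso1*", lay_star$end[g_row] - 2000L,
                    2000L + 4845L + 2000L)
  rp3 <- read_to_segment_path(rd3, genome, index = idx)
  expect_equal(rp3$path, c("g+", "d+", "e+"))
})

test_that("junction support follows the flank-coverage rule", {
  genome <- rs_genome()
  idx <- rs_index()
  fx <- genome$fixture
  lay <- genome$layouts[["iso1"]]
  p_bc <- lay$end[2L]
  ## 350/500 bp on each side: supports (0.70 >= 0.60)
  rd_yes <- iso_substr(genome, "iso1", p_bc - 350L, 700L)
  ## 250/500 bp on the left side only: does not support (0.50 < 0.60)
  rd_no <- iso_substr(genome, "iso1", p_bc - 250L, 750L)
  paths <- reads_to_segment_paths(c(yes = rd_yes, no = rd_no), genome,
                                  index = rs_index())
  js <- junction_support(paths["yes"], fx$graph)
  key_bc <- canonical_junction("b+", "c+")
  expect_equal(js$support[js$junction == key_bc], 1L)
  js_no <- junction_support(paths["no"], fx$graph)
  expect_equal(js_no$support[js_no$junction == key_bc], 0L)
})

test_that("a uniform read pool supports all twelve junctions", {
  genome <- rs_genome()
  fx <- genome$fixture
  rds <- simulate_long_reads(genome, n = 80L, length_mean = 25000,
                             length_sd = 5000, error_rate = 0, seed = 8)
  paths <- reads_to_segment_paths(rds$reads, genome, index = rs_index())
  js <- junction_support(paths, fx$graph)
  expect_equal(nrow(js), 12L)
  expect_true(all(js$support > 0L))
})

test_that("unique subpaths reproduce the published diagnostic fragments", {
  fx <- zm9_fixture()
  walks <- lapply(fx$isoforms, `[[`, "walk")
  ## c-d-e-b-c univocally defines isoI
  p1 <- c("c+", "d+", "e+", "b+", "c+")
  hits <- names(which(vapply(walks, mitoforms:::walk_contains_path, TRUE,
                             path = p1)))
  expect_equal(hits, "isoI")
  ## g-d-e-b-c occurs only in iso1*
  p2 <- c("g+", "d+", "e+", "b+", "c+")
  hits2 <- names(which(vapply(walks, mitoforms:::walk_contains_path, TRUE,
                              path = p2)))
  expect_equal(hits2, "iso1*")
  ## every isoform has a unique fragment in this architecture
  us <- unique_subpaths(fx$isoforms, fx$graph)
  expect_true(all(!is.na(us$unique_path)))
  ## the isoI fragment found must not be longer (in bp) than c-d-e-b-c
  expect_lte(us$min_bp[us$isoform == "isoI"],
             mitoforms:::subpath_min_bp(p1, fx$graph))
})

test_that("a repeat-free circle is confirmed by any single segment", {
  segs <- segment_table(c("x", "y"), c(100L, 200L))
  g <- build_segment_graph(segs, c("x>y", "y>x"))
  iso <- isoform("circ", c("x", "y"), graph = g)
  us <- unique_subpaths(list(iso), g)
  expect_equal(us$n_segments, 1L)
  expect_equal(us$min_bp, 1)
})

test_that("confirmation counts respect read provenance (no false confirmation)", {
  genome <- rs_genome()
  fx <- genome$fixture
  us <- unique_subpaths(fx$isoforms, fx$graph)
  rds <- simulate_long_reads(genome, weights = c(iso2 = 1), n = 40L,
                             length_mean = 30000, length_sd = 5000,
                             error_rate = 0, seed = 9)
  paths <- reads_to_segment_paths(rds$reads, genome, index = rs_index())
  conf <- confirm_isoforms(paths, us, max_read_len = max(nchar(rds$reads)))
  ## reads sampled only from iso2 can never contain another isoform's
  ## unique fragment
  expect_true(all(conf$support[conf$isoform != "iso2"] == 0L))
  ## empty read pool: all zero
  conf0 <- confirm_isoforms(list(), us)
  expect_true(all(conf0$support == 0L))
})

test_that("junction support and confirmation are strand-invariant", {
  genome <- rs_genome()
  fx <- genome$fixture
  rds <- simulate_long_reads(genome, n = 30L, length_mean = 20000,
                             length_sd = 3000, error_rate = 0, seed = 10)
  flipped <- vapply(rds$reads, rc, "")
  names(flipped) <- names(rds$reads)
  p1 <- reads_to_segment_paths(rds$reads, genome, index = rs_index())
  p2 <- reads_to_segment_paths(flipped, genome, index = rs_index())
  js1 <- junction_support(p1, fx$graph)
  js2 <- junction_support(p2, fx$graph)
  expect_equal(js1, js2)
  us <- unique_subpaths(fx$isoforms, fx$graph)
  expect_equal(confirm_isoforms(p1, us), confirm_isoforms(p2, us))
})
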