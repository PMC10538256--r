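## The canonical nine-segment (ZM-9) fixture: a constructive reconstruction
## of an eelgrass-like multipartite mitogenome in which a three-edge assembly
## graph plus two recombinationally active direct repeats cut the genome into
## nine segments a..i joined by 12 junctions, carrying eight circular
## isoforms (three master circles, five subgenomes).

ZM9_DEFAULT_LENGTHS <- c(
  a = 30000L, b = 3695L, c = 20000L, d = 4845L, e = 70665L,
  f = 16404L, g = 12000L, h = 18560L, i = 2339L
)

## Edge composition of the underlying assembly graph. The common edge runs
## a-b-c-d-e-b-f (Rep2 = b twice, Rep1 = d once); the large alternative edge
## g-d-h carries the second Rep1 copy; the small alternative edge is i alone.
ZM9_EDGES <- list(
  common = c("a", "b", "c", "d", "e", "b", "f"),
  alt_large = c("g", "d", "h"),
  alt_small = c("i")
)
ZM9_EDGE_LENGTHS <- c(common = 149304L, alt_large = 35405L, alt_small = 2339L)

ZM9_WALKS <- list(
  iso1    = c("a", "b", "c", "d", "e", "b", "f", "g", "d", "h"),
  iso2    = c("a", "b", "c", "d", "e", "b", "f", "i"),
  `iso1*` = c("a", "b", "f", "g", "d", "e", "b", "c", "d", "h"),
  isoI    = c("b", "c", "d", "e"),
  isoII   = c("a", "b", "f", "i"),
  isoIII  = c("a", "b", "c", "d", "h"),
  isoIV   = c("b", "f", "g", "d", "e"),
  isoV    = c("a", "b", "f", "g", "d", "h")
)

ZM9_SUBGENOMES <- c("isoI", "isoII", "isoIII", "isoIV", "isoV")
ZM9_MASTERS <- c("iso1", "iso2", "iso1*")

#' The nine-segment reference fixture
#'
#' Builds the canonical nine-segment architecture: segments `a`..`i` with
#' `d` = Rep1 (4,845 bp, one copy in the common assembly edge and one in the
#' large alternative edge) and `b` = Rep2 (3,695 bp, both copies in the
#' common edge), the 12 junctions connecting them, and the eight circular
#' isoforms they support (master circles iso1, iso2, iso1* and subgenomes
#' isoI..isoV). Free segment lengths default to values that make the three
#' assembly edge lengths come out at 149,304 / 35,405 / 2,339 bp.
#'
#' @param segment_lengths optional named vector overriding default segment
#'   lengths (all nine, or a subset). Overrides that break the edge-length
#'   sums are rejected unless `relax_edges = TRUE`.
#' @param relax_edges if `TRUE`, edge-sum constraints are not enforced
#'   (useful for scaled-down toy genomes).
#' @return a list with elements `graph` (a [build_segment_graph()] object),
#'   `isoforms` (named list of the 8 truth [isoform()]s), `edges` (edge
#'   composition), `edge_lengths`, and `iso2_note` describing the known
#'   discrepancy between the arithmetic iso2 length and the published one.
#' @export
zm9_fixture <- function(segment_lengths = NULL, relax_edges = FALSE) {
  lens <- ZM9_DEFAULT_LENGTHS
  if (!is.null(segment_lengths)) {
    bad <- setdiff(names(segment_lengths), names(lens))
    if (length(bad)) stop("unknown segment id(s): ", paste(bad, collapse = ", "))
    lens[names(segment_lengths)] <- as.integer(segment_lengths)
  }
  if (!relax_edges) {
    edge_sums <- vapply(ZM9_EDGES, function(e) sum(lens[e]), 0)
    off <- edge_sums != ZM9_EDGE_LENGTHS
    if (any(off))
      stop("segment lengths violate edge sum(s): ",
           paste0(names(edge_sums)[off], " = ", edge_sums[off],
                  " (expected ", ZM9_EDGE_LENGTHS[off], ")", collapse = "; "))
  }
  segs <- segment_table(
    id = names(lens),
    length = lens,
    is_repeat = names(lens) %in% c("b", "d"),
    repeat_name = c(a = NA, b = "Rep2", c = NA, d = "Rep1", e = NA,
                    f = NA, g = NA, h = NA, i = NA)[names(lens)]
  )
  jn <- c("a>b", "b>c", "c>d", "d>e", "e>b", "b>f",
          "f>g", "g>d", "d>h", "h>a", "f>i", "i>a")
  graph <- build_segment_graph(segs, jn,
                               repeat_copies = c(a = 1L, b = 2L, c = 1L, d = 2L,
                                                 e = 1L, f = 1L, g = 1L, h = 1L,
                                                 i = 1L))
  isoforms <- lapply(names(ZM9_WALKS), function(nm)
    isoform(nm, ZM9_WALKS[[nm]], graph = graph, provenance = "fixture"))
  names(isoforms) <- names(ZM9_WALKS)
  iso2_arith <- sum(lens[os_id(isoforms$iso2$walk)])
  list(
    graph = graph,
    isoforms = isoforms,
    edges = ZM9_EDGES,
    edge_lengths = vapply(ZM9_EDGES, function(e) sum(lens[e]), 0),
    masters = ZM9_MASTERS,
    subgenomes = ZM9_SUBGENOMES,
    iso2_note = paste0(
      "iso2 arithmetic length ", iso2_arith, " bp (common edge + small ",
      "alternative edge); the published 156,143 bp exceeds this by ",
      156143L - iso2_arith, " bp and is not reproducible from edge arithmetic"
    )
  )
}
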