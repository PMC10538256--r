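## Core domain model: segments, oriented segments, canonical junctions,
## segment multigraphs and circular isoforms.
##
## An oriented segment is written as "<id>+" or "<id>-". A junction l>r means
## "r immediately follows l along one strand"; read on the other strand the
## same adjacency is flip(r)>flip(l), and exactly one of the two writings (the
## lexicographically smaller, with "+" sorting before "-") is stored.

#' Create a segment table
#'
#' @param id character vector of segment labels (unique).
#' @param length integer vector of segment lengths in bp (>= 1).
#' @param is_repeat logical vector; repeat segments are those present in more
#'   than one genomic copy.
#' @param repeat_name optional labels (e.g. "Rep1") for repeat segments;
#'   must be `NA` for non-repeat segments.
#' @return a `data.frame` with columns id, length, is_repeat, repeat_name.
#' @export
segment_table <- function(id, length, is_repeat = FALSE, repeat_name = NA_character_) {
  df <- data.frame(
    id = as.character(id),
    length = as.integer(length),
    is_repeat = rep_len(as.logical(is_repeat), base::length(id)),
    repeat_name = rep_len(as.character(repeat_name), base::length(id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$id)) stop("segment ids must be unique")
  if (any(df$length < 1L)) stop("segment lengths must be >= 1")
  bad <- df$is_repeat != !is.na(df$repeat_name)
  if (any(bad))
    stop("repeat segments must carry a repeat_name and non-repeat segments none: ",
         paste(df$id[bad], collapse = ", "))
  df
}

## ---- oriented segment helpers ------------------------------------------

os_id <- function(os) sub("[+-]$", "", os)
os_strand <- function(os) substring(os, nchar(os))

#' Flip the strand of oriented segments
#' @param os character vector of oriented segment ids like `"a+"`.
#' @return the same segments on the opposite strand.
#' @export
os_flip <- function(os) {
  paste0(os_id(os), ifelse(os_strand(os) == "+", "-", "+"))
}

## ---- junctions -----------------------------------------------------------

junction_key <- function(left, right) paste(left, right, sep = ">")

junction_split <- function(key) {
  parts <- strsplit(key, ">", fixed = TRUE)
  list(left = vapply(parts, `[`, "", 1L), right = vapply(parts, `[`, "", 2L))
}

#' Canonical form of junctions
#'
#' A junction and its strand-flip describe the same adjacency; the canonical
#' representative is the lexicographically smaller of the two writings, with
#' `+` ordered before `-` within a segment id.
#'
#' @param left,right oriented segment ids (vectors of equal length).
#' @return character vector of canonical junction keys `"l>r"`.
#' @export
canonical_junction <- function(left, right) {
  a <- junction_key(left, right)
  b <- junction_key(os_flip(right), os_flip(left))
  ifelse(radix_leq(a, b), a, b)
}

## Byte-order (C locale) a <= b, elementwise, independent of the session
## collation; "+" < "-" in ASCII so forward sorts before reverse.
radix_leq <- function(a, b) {
  n <- length(a)
  x <- c(a, b)
  r <- integer(2L * n)
  r[order(x, method = "radix")] <- seq_len(2L * n)
  a == b | r[seq_len(n)] < r[n + seq_len(n)]
}

## ---- segment graph -------------------------------------------------------

#' Build a segment multigraph
#'
#' @param segments a segment table from [segment_table()].
#' @param junctions a 2-column data.frame (left, right) of oriented segment
#'   ids, or a character vector of `"l>r"` keys. Unoriented ids are taken as
#'   forward. Junctions are canonicalized and duplicates collapsed.
#' @param repeat_copies optional named integer vector: genomic copy count per
#'   repeat segment id (defaults to 2 for repeat segments, 1 otherwise).
#' @return an object of class `segment_graph`.
#' @export
build_segment_graph <- function(segments, junctions, repeat_copies = NULL) {
  if (is.character(junctions)) {
    js <- junction_split(junctions)
    junctions <- data.frame(left = js$left, right = js$right,
                            stringsAsFactors = FALSE)
  }
  orient <- function(x) ifelse(grepl("[+-]$", x), x, paste0(x, "+"))
  left <- orient(junctions$left)
  right <- orient(junctions$right)
  unknown <- setdiff(unique(c(os_id(left), os_id(right))), segments$id)
  if (length(unknown) > 0L) {
    bad <- os_id(left) %in% unknown | os_id(right) %in% unknown
    stop("junction references undeclared segment(s) ",
         paste(unknown, collapse = ", "), " in: ",
         paste(junction_key(left[bad], right[bad]), collapse = ", "))
  }
  keys <- sort(unique(canonical_junction(left, right)), method = "radix")
  js <- junction_split(keys)
  if (is.null(repeat_copies)) {
    repeat_copies <- setNames(ifelse(segments$is_repeat, 2L, 1L), segments$id)
  }
  structure(
    list(
      segments = segments,
      junctions = data.frame(left = js$left, right = js$right, key = keys,
                             stringsAsFactors = FALSE),
      repeat_copies = repeat_copies
    ),
    class = "segment_graph"
  )
}

#' @export
print.segment_graph <- function(x, ...) {
  cat("segment_graph:", nrow(x$segments), "segments,",
      nrow(x$junctions), "junctions\n")
  cat("  segments:", paste(x$segments$id, collapse = " "), "\n")
  reps <- x$segments$id[x$segments$is_repeat]
  if (length(reps))
    cat("  repeats: ", paste0(reps, " (", x$segments$repeat_name[x$segments$is_repeat],
                              ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}

graph_has_junction <- function(graph, left, right) {
  canonical_junction(left, right) %in% graph$junctions$key
}

segment_length <- function(graph, ids) {
  graph$segments$length[match(ids, graph$segments$id)]
}

## ---- isoforms ------------------------------------------------------------

#' Create an isoform (a circular walk of oriented segments)
#'
#' @param name isoform label.
#' @param walk character vector of oriented segment ids, read circularly;
#'   unoriented ids are taken as forward.
#' @param graph the governing [build_segment_graph()] object; if supplied the
#'   walk is validated: every adjacent pair (including the wrap-around) must
#'   be a junction of the graph and no junction may be used twice
#'   (junction-simplicity).
#' @param provenance one of `"enumerated"`, `"fixture"`, `"user"`.
#' @return an object of class `isoform`.
#' @export
isoform <- function(name, walk, graph = NULL, provenance = "user") {
  walk <- ifelse(grepl("[+-]$", walk), walk, paste0(walk, "+"))
  if (length(walk) == 0L) stop("isoform walk must be non-empty")
  if (!is.null(graph)) {
    nxt <- c(walk[-1L], walk[1L])
    keys <- canonical_junction(walk, nxt)
    missing <- !(keys %in% graph$junctions$key)
    if (any(missing))
      stop("walk adjacency not a graph junction: ",
           paste(junction_key(walk[missing], nxt[missing]), collapse = ", "))
    if (anyDuplicated(keys))
      stop("walk reuses junction(s): ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  structure(list(name = name, walk = walk, provenance = provenance),
            class = "isoform")
}

#' @export
print.isoform <- function(x, ...) {
  cat("isoform", x$name, "[", paste(x$walk, collapse = " "), "] (",
      x$provenance, ")\n")
  invisible(x)
}

#' Length of a circular isoform in bp
#'
#' Each occurrence of a segment in the walk contributes its full length, so a
#' master circle counts its repeat segment once per traversal.
#'
#' @param iso an [isoform()].
#' @param graph the governing segment graph (supplies segment lengths).
#' @return total length in bp.
#' @export
isoform_length <- function(iso, graph) {
  sum(segment_length(graph, os_id(iso$walk)))
}

#' Junctions used by an isoform walk
#' @param iso an [isoform()].
#' @return character vector of canonical junction keys (with wrap-around).
#' @export
isoform_junctions <- function(iso) {
  walk <- iso$walk
  canonical_junction(walk, c(walk[-1L], walk[1L]))
}

#' Segment membership matrix of a set of isoforms
#'
#' Entry (s, k) counts how often segment s occurs in the walk of isoform k.
#' Under a stoichiometry vector sigma over the isoforms, the expected segment
#' copy vector is `membership %*% sigma`.
#'
#' @param isoforms list of [isoform()] objects over one graph.
#' @param graph the governing segment graph (fixes the row order).
#' @return integer matrix, segments x isoforms.
#' @export
membership_matrix <- function(isoforms, graph) {
  ids <- graph$segments$id
  m <- matrix(0L, nrow = length(ids), ncol = length(isoforms),
              dimnames = list(ids, vapply(isoforms, `[[`, "", "name")))
  for (k in seq_along(isoforms)) {
    tab <- table(os_id(isoforms[[k]]$walk))
    m[names(tab), k] <- as.integer(tab)
  }
  m
}

## ---- canonical walk form (dedup under rotation and strand flip) ----------

walk_rotations <- function(walk) {
  n <- length(walk)
  lapply(seq_len(n), function(i) walk[c(i:n, seq_len(i - 1L))])
}

#' Canonical representative of a circular walk
#'
#' Two walks describe the same circular molecule if one is a rotation of the
#' other or of its reverse complement. The canonical form is the
#' lexicographically least rotation over both strands.
#'
#' @param walk character vector of oriented segment ids.
#' @return character vector, the canonical walk.
#' @export
canonical_walk <- function(walk) {
  rev_walk <- rev(os_flip(walk))
  cands <- c(walk_rotations(walk), walk_rotations(rev_walk))
  keys <- vapply(cands, paste, "", collapse = ",")
  cands[[order(keys, method = "radix")[1L]]]
}

walk_signature <- function(walk) paste(canonical_walk(walk), collapse = ",")
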