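## Long-read support for the segment architecture: projection of reads onto
## segment paths, junction support counting under a flank-coverage rule, and
## isoform confirmation through isoform-unique subpaths.

## Layout of an isoform doubled (for wrap-around spans): rows of
## (segment, strand, start, end) with the second copy offset by the
## circumference.
doubled_layout <- function(layout) {
  L <- max(layout$end)
  second <- layout
  second$start <- second$start + L
  second$end <- second$end + L
  rbind(layout, second)
}

#' Project a long read onto a segment path
#'
#' Aligns the read against every isoform sequence of a synthetic (or
#' otherwise laid-out) genome, keeps the best-scoring single local
#' alignment, and converts its span into the ordered list of oriented
#' segments it traverses. The path is reported in the isoform's forward
#' orientation regardless of the read's strand, so paths are directly
#' comparable to canonical walks.
#'
#' @param read read sequence (character).
#' @param genome a [synth_genome()] result (`isoform_seqs` + `layouts`).
#' @param k anchor k-mer length.
#' @param min_identity reject alignments below this identity.
#' @param index optional precomputed [genome_read_index()]; computed on the
#'   fly otherwise (index once when projecting many reads).
#' @return object of class `read_path`: list with `path` (oriented segment
#'   ids), `molecule`, `strand`, `span` (1-based inclusive on the doubled
#'   molecule), `seg_bp` (bp of the span inside each path entry),
#'   `boundaries` (isoform coordinate of each internal junction),
#'   `identity`; or NULL if the read does not align.
#' @export
read_to_segment_path <- function(read, genome, k = 13L, min_identity = 0.80,
                                 index = NULL) {
  if (is.null(index)) index <- genome_read_index(genome, k = k)
  best <- NULL
  for (nm in names(index)) {
    mm <- match_read(read, index[[nm]], min_id = min_identity)
    if (is.null(mm) || mm$identity < min_identity) next
    if (is.null(best) || mm$score > best$score) {
      mm$molecule <- nm
      best <- mm
    }
  }
  if (is.null(best)) return(NULL)
  lay <- doubled_layout(genome$layouts[[best$molecule]])
  s0 <- best$ref_start - 1L   # 0-based half-open span
  e0 <- best$ref_end
  hit <- which(lay$end > s0 & lay$start < e0)
  path <- paste0(lay$segment[hit], lay$strand[hit])
  seg_bp <- pmin(lay$end[hit], e0) - pmax(lay$start[hit], s0)
  boundaries <- if (length(hit) > 1L) lay$end[hit[-length(hit)]] else numeric(0)
  structure(list(read = NA_character_, path = path, molecule = best$molecule,
                 strand = best$strand, span = c(best$ref_start, best$ref_end),
                 seg_bp = seg_bp, boundaries = boundaries,
                 identity = best$identity),
            class = "read_path")
}

#' Project many reads onto segment paths
#'
#' @param reads named character vector.
#' @param genome a [synth_genome()] result.
#' @param k anchor k-mer length.
#' @param index optional precomputed [genome_read_index()].
#' @param ... passed to [read_to_segment_path()].
#' @return list of `read_path` objects (unaligned reads are kept as NULL
#'   entries and tallied in the `n_unaligned` attribute).
#' @export
reads_to_segment_paths <- function(reads, genome, k = 13L, index = NULL, ...) {
  if (is.null(index)) index <- genome_read_index(genome, k = k)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    rp <- read_to_segment_path(reads[[i]], genome, index = index, ...)
    if (!is.null(rp)) rp$read <- names(reads)[i]
    out[[i]] <- rp
  }
  names(out) <- names(reads)
  attr(out, "n_unaligned") <- sum(vapply(out, is.null, TRUE))
  out
}

#' Index the doubled isoform sequences of a genome for read projection
#' @param genome a [synth_genome()] result.
#' @param k anchor k-mer length.
#' @return named list of [seq_index()] objects (doubled sequences, so
#'   wrap-around alignments stay contiguous).
#' @export
genome_read_index <- function(genome, k = 13L) {
  lapply(genome$isoform_seqs, function(s) seq_index(paste0(s, s), k = k))
}

#' Count long-read support per junction
#'
#' A read supports a junction when its single alignment covers at least
#' `min_frac` of each of the two `flank` bp windows around the junction
#' point. Each read counts at most once per junction.
#'
#' @param read_paths list of `read_path` objects (NULLs allowed).
#' @param graph the governing segment graph (fixes the junction universe).
#' @param flank flank window in bp.
#' @param min_frac minimum covered fraction of each window.
#' @return data.frame `junction`, `support` over all graph junctions.
#' @export
junction_support <- function(read_paths, graph, flank = 500L,
                             min_frac = 0.60) {
  counts <- setNames(integer(nrow(graph$junctions)), graph$junctions$key)
  for (rp in read_paths) {
    if (is.null(rp) || length(rp$path) < 2L) next
    s0 <- rp$span[1L] - 1L; e0 <- rp$span[2L]
    seen <- character(0)
    for (bi in seq_along(rp$boundaries)) {
      p <- rp$boundaries[bi]
      covL <- min(p, e0) - max(p - flank, s0)
      covR <- min(p + flank, e0) - max(p, s0)
      if (covL / flank >= min_frac && covR / flank >= min_frac) {
        key <- canonical_junction(rp$path[bi], rp$path[bi + 1L])
        if (!(key %in% seen) && key %in% names(counts)) {
          counts[key] <- counts[key] + 1L
          seen <- c(seen, key)
        }
      }
    }
  }
  data.frame(junction = names(counts), support = as.integer(counts),
             stringsAsFactors = FALSE)
}

## Does circular walk W contain linear oriented path P (allowing wraps and
## either strand)?
walk_contains_path <- function(walk, path) {
  lp <- length(path)
  reps <- ceiling(lp / length(walk)) + 1L
  ext <- rep(walk, reps)
  rev_path <- rev(os_flip(path))
  for (s in seq_len(length(walk))) {
    win <- ext[s:(s + lp - 1L)]
    if (identical(win, path) || identical(win, rev_path)) return(TRUE)
  }
  FALSE
}

## Does linear read path P contain linear subpath Q (either strand)?
path_contains_subpath <- function(path, sub) {
  lq <- length(sub)
  if (lq > length(path)) return(FALSE)
  rev_sub <- rev(os_flip(sub))
  for (s in seq_len(length(path) - lq + 1L)) {
    win <- path[s:(s + lq - 1L)]
    if (identical(win, sub) || identical(win, rev_sub)) return(TRUE)
  }
  FALSE
}

#' Minimal isoform-unique subpaths and confirming read lengths
#'
#' For every isoform, finds the contiguous fragment of its circular walk
#' (up to one full turn plus one segment) that occurs in no other isoform
#' on either strand and whose confirming read is shortest. The minimal
#' confirming read length counts all internal segments in full plus 1 bp
#' reaching into each terminal segment.
#'
#' @param isoforms list of [isoform()] objects.
#' @param graph the governing segment graph.
#' @return data.frame `isoform`, `unique_path` (comma-joined oriented ids;
#'   NA when the isoform has no unique fragment), `n_segments`, `min_bp`.
#' @export
unique_subpaths <- function(isoforms, graph) {
  walks <- lapply(isoforms, `[[`, "walk")
  nms <- vapply(isoforms, `[[`, "", "name")
  res <- lapply(seq_along(isoforms), function(i) {
    w <- walks[[i]]
    L <- length(w)
    best_bp <- Inf; best_path <- NULL
    for (len in seq_len(L + 1L)) {
      ext <- rep(w, 2L)
      for (s in seq_len(L)) {
        p <- ext[s:(s + len - 1L)]
        others <- vapply(seq_along(walks)[-i], function(j)
          walk_contains_path(walks[[j]], p), TRUE)
        if (!any(others)) {
          bp <- subpath_min_bp(p, graph)
          if (bp < best_bp) { best_bp <- bp; best_path <- p }
        }
      }
      ## no early exit: a longer fragment of short segments can need a
      ## shorter confirming read than a short fragment spanning a long
      ## internal segment
    }
    data.frame(isoform = nms[i],
               unique_path = if (is.null(best_path)) NA_character_ else
                 paste(best_path, collapse = ","),
               n_segments = if (is.null(best_path)) NA_integer_ else
                 length(best_path),
               min_bp = if (is.null(best_path)) NA_real_ else best_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## bp needed for a read to pin down path p: internal segments in full plus
## 1 bp inside each terminal segment (a single-segment path needs 1 bp).
subpath_min_bp <- function(p, graph) {
  if (length(p) == 1L) return(1)
  if (length(p) == 2L) return(2)
  sum(segment_length(graph, os_id(p[-c(1L, length(p))]))) + 2
}

#' Confirm isoforms by unique-fragment reads
#'
#' Counts reads whose segment path contains each isoform's unique fragment.
#' Isoforms whose minimal confirming read length exceeds the longest
#' observed read are flagged as requiring longer reads.
#'
#' @param read_paths list of `read_path` objects.
#' @param usubs result of [unique_subpaths()].
#' @param max_read_len longest read length available (bp); used only for
#'   the flag.
#' @return data.frame `isoform`, `support`, `min_bp`,
#'   `requires_longer_reads`.
#' @export
confirm_isoforms <- function(read_paths, usubs, max_read_len = Inf) {
  support <- integer(nrow(usubs))
  for (rp in read_paths) {
    if (is.null(rp)) next
    for (i in seq_len(nrow(usubs))) {
      if (is.na(usubs$unique_path[i])) next
      sub <- strsplit(usubs$unique_path[i], ",", fixed = TRUE)[[1]]
      if (path_contains_subpath(rp$path, sub))
        support[i] <- support[i] + 1L
    }
  }
  data.frame(isoform = usubs$isoform, support = support,
             min_bp = usubs$min_bp,
             requires_longer_reads = !is.na(usubs$min_bp) &
               usubs$min_bp > max_read_len,
             stringsAsFactors = FALSE)
}
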