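## Format plumbing: GFA 1.0 for segment graphs, FASTA via Biostrings, BED
## (0-based half-open) and headered TSV with a schema-version comment line.

TSV_SCHEMA <- "#mitoforms-tsv-v1"

#' Write a segment graph as GFA 1.0
#'
#' Segments become S lines (sequence `*` unless supplied, with an `LN` tag)
#' and junctions become L lines with a `0M` overlap.
#'
#' @param graph a [build_segment_graph()] object.
#' @param path output file.
#' @param sequences optional named character vector of segment sequences.
#' @export
write_gfa <- function(graph, path, sequences = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (i in seq_len(nrow(graph$segments))) {
    id <- graph$segments$id[i]
    seq <- if (!is.null(sequences) && id %in% names(sequences))
      sequences[[id]] else "*"
    writeLines(sprintf("S\t%s\t%s\tLN:i:%d", id, seq,
                       graph$segments$length[i]), con)
  }
  j <- graph$junctions
  for (i in seq_len(nrow(j))) {
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M",
                       os_id(j$left[i]), os_strand(j$left[i]),
                       os_id(j$right[i]), os_strand(j$right[i])), con)
  }
  invisible(path)
}

#' Read a segment graph from GFA 1.0
#'
#' @param path GFA file with S lines (LN tag or explicit sequence) and L
#'   lines; `repeat_ids` optionally marks repeat segments.
#' @param repeat_ids named character vector mapping segment id to repeat
#'   name (e.g. `c(d = "Rep1")`).
#' @return list with `graph` and `sequences` (NULL when all S lines are
#'   `*`).
#' @export
read_gfa <- function(path, repeat_ids = NULL) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  s <- fields[vapply(fields, `[`, "", 1L) == "S"]
  l <- fields[vapply(fields, `[`, "", 1L) == "L"]
  ids <- vapply(s, `[`, "", 2L)
  seqs <- vapply(s, `[`, "", 3L)
  lens <- vapply(seq_along(s), function(i) {
    ln <- grep("^LN:i:", s[[i]], value = TRUE)
    if (length(ln)) as.integer(sub("^LN:i:", "", ln[1L]))
    else nchar(seqs[i])
  }, 0L)
  segs <- segment_table(
    id = ids, length = lens,
    is_repeat = if (is.null(repeat_ids)) FALSE else ids %in% names(repeat_ids),
    repeat_name = if (is.null(repeat_ids)) NA_character_ else
      unname(repeat_ids[ids]))
  jn <- data.frame(
    left = paste0(vapply(l, `[`, "", 2L), vapply(l, `[`, "", 3L)),
    right = paste0(vapply(l, `[`, "", 4L), vapply(l, `[`, "", 5L)),
    stringsAsFactors = FALSE)
  list(graph = build_segment_graph(segs, jn),
       sequences = if (all(seqs == "*")) NULL else setNames(seqs, ids))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a BED file (0-based half-open)
#' @param df data.frame whose first three columns are chrom/start/end (a
#'   `segment` or `name` column is written as the BED name field).
#' @param path output file.
#' @param chrom reference name used when `df` has no chrom column.
#' @export
write_bed <- function(df, path, chrom = "ref") {
  name <- if ("segment" %in% names(df)) df$segment
  else if ("name" %in% names(df)) df$name else "."
  out <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a data.frame (start/end 0-based half-open)
#' @param path BED file.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df
}

#' Write a headered TSV with a schema-version comment line
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TSV_SCHEMA, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path TSV file.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Isoform walks as a TSV-ready data.frame
#' @param isoforms list of [isoform()] objects.
#' @param graph governing segment graph.
#' @param classification optional [classify_isoforms()] result.
#' @return data.frame `name`, `class`, `walk` (comma-joined oriented ids),
#'   `length_bp`.
#' @export
isoform_table <- function(isoforms, graph, classification = NULL) {
  nms <- vapply(isoforms, `[[`, "", "name")
  cls <- if (is.null(classification)) NA_character_ else
    ifelse(nms %in% classification$masters, "master", "subgenome")
  data.frame(
    name = nms,
    class = cls,
    walk = vapply(isoforms, function(i) paste(i$walk, collapse = ","), ""),
    length_bp = vapply(isoforms, isoform_length, 0, graph = graph),
    stringsAsFactors = FALSE)
}
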