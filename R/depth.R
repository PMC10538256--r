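## Per-position short-read depth over the circular reference, homology
## masking of NUMT/plastid-shared intervals, and normalized per-segment copy
## number. Coordinates are 0-based half-open (BED convention) throughout.

#' Construct a depth profile
#'
#' @param depth integer vector of per-position coverage.
#' @param mask optional data.frame (`start`, `end`, 0-based half-open) of
#'   positions excluded from depth statistics (NUMT / plastid-shared).
#' @return object of class `depth_profile`.
#' @export
depth_profile <- function(depth, mask = NULL) {
  if (any(depth < 0)) stop("depth must be non-negative")
  if (!is.null(mask) && nrow(mask) > 0L) {
    if (any(mask$start < 0L) || any(mask$end > length(depth)))
      stop("mask outside reference")
  } else {
    mask <- data.frame(start = integer(), end = integer())
  }
  structure(list(length = length(depth), depth = as.numeric(depth),
                 mask = mask),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile: length", x$length,
      "| median depth", median(x$depth),
      "| masked", sum(x$mask$end - x$mask$start), "bp\n")
  invisible(x)
}

mask_logical <- function(profile) {
  m <- rep(FALSE, profile$length)
  for (i in seq_len(nrow(profile$mask)))
    m[(profile$mask$start[i] + 1L):profile$mask$end[i]] <- TRUE
  m
}

#' Merge depth over two linearizations of a circular reference
#'
#' Aligning to a single linearization depresses coverage at the break
#' point. Given per-position depth from two linear forms of the same circle
#' whose break points differ by `rotation_offset`, back-maps the second to
#' the first's coordinates and takes the per-position maximum, removing the
#' edge artifact.
#'
#' @param depth1 depth vector on linearization 1.
#' @param depth2 depth vector on linearization 2, whose position 0
#'   corresponds to position `rotation_offset` of linearization 1.
#' @param rotation_offset strictly positive rotation between the two break
#'   points.
#' @return a [depth_profile()] on linearization-1 coordinates.
#' @export
circular_depth <- function(depth1, depth2, rotation_offset) {
  if (length(depth1) != length(depth2))
    stop("linearizations must have equal length")
  n <- length(depth1)
  rotation_offset <- as.integer(rotation_offset) %% n
  if (rotation_offset == 0L)
    stop("rotation offset must be non-zero: the two break points must differ")
  ## depth2[i] measures circle position (i - 1 + offset) %% n
  back <- integer(n)
  idx <- ((seq_len(n) - 1L + rotation_offset) %% n) + 1L
  back[idx] <- depth2
  depth_profile(pmax(depth1, back))
}

#' Mask mitochondrial positions shared with other genomes
#'
#' Finds intervals of the mitochondrial reference with near-identical copies
#' in nuclear or plastid sequence using an exact k-mer seed scan with
#' ungapped extension (the same HSP model as [find_repeat_pairs()]), and
#' merges them into a mask. A precomputed mask (e.g. from an external
#' aligner) can be supplied instead via `precomputed`.
#'
#' @param mito_reference character string.
#' @param other_sequences character vector of nuclear/plastid sequences.
#' @param min_identity minimum identity of a masked interval.
#' @param min_len minimum masked interval length in bp.
#' @param seed_len k-mer length for diagonal selection.
#' @param precomputed optional data.frame (`start`, `end`) that is merged
#'   and returned as-is.
#' @return data.frame (`start`, `end`), 0-based half-open, merged.
#' @export
mask_homology <- function(mito_reference, other_sequences = NULL,
                          min_identity = 0.85, min_len = 200L,
                          seed_len = 14L, precomputed = NULL) {
  if (!is.null(precomputed)) {
    m <- merge_intervals(cbind(precomputed$start, precomputed$end))
    return(data.frame(start = unname(m[, 1L]), end = unname(m[, 2L])))
  }
  if (is.null(other_sequences) || length(other_sequences) == 0L)
    return(data.frame(start = integer(), end = integer()))
  xm <- dna_to_int(as.character(mito_reference))
  word <- min(seed_len, min_len)
  hits <- NULL
  for (os in other_sequences) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") as.character(os) else revcomp_chr(as.character(os))
      xo <- dna_to_int(s)
      offs <- seed_diagonals(xm, xo, k = seed_len)
      for (off in offs) {
        w <- scan_diagonal(xm, xo, off, min_identity, min_len, word)
        if (!is.null(w)) hits <- rbind(hits, w[, 1:2, drop = FALSE])
      }
    }
  }
  if (is.null(hits))
    return(data.frame(start = integer(), end = integer()))
  m <- merge_intervals(cbind(hits[, 1L] - 1L, hits[, 2L]))
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' Per-replicon target coverage from single-copy nuclear genes
#'
#' The sequencing depth of one nuclear replicon: mean of the per-gene mean
#' coverages of single-copy nuclear genes, divided by two because the
#' nuclear genome is diploid.
#'
#' @param gene_depths numeric vector of per-gene mean depths.
#' @return a single number.
#' @export
target_coverage <- function(gene_depths) {
  if (length(gene_depths) == 0L) stop("no single-copy gene depths supplied")
  mean(gene_depths) / 2
}

#' Per-segment copy number from masked median depth
#'
#' For every segment, the median depth over its unmasked positions divided
#' by the per-sample target coverage. The median of an even count of values
#' is the lower middle value ([median_low()]). Repeat segments are measured
#' over their single reference representation, so their copy number counts
#' all genomic copies.
#'
#' @param profile a [depth_profile()] over the segment reference.
#' @param segments_bed data.frame `segment`, `start`, `end`.
#' @param mask optional data.frame (`start`, `end`) overriding the
#'   profile's own mask.
#' @param target per-replicon target coverage (> 0).
#' @return data.frame with `segment`, `raw_median`, `copy_number`,
#'   `unmasked_bp`, `qc_pass` (FALSE when a segment is fully masked; its
#'   copy number is then `NA`).
#' @export
segment_copy_number <- function(profile, segments_bed, mask = NULL,
                                target) {
  if (target <= 0) stop("target coverage must be > 0")
  if (!is.null(mask)) profile <- depth_profile(profile$depth, mask)
  masked <- mask_logical(profile)
  res <- lapply(seq_len(nrow(segments_bed)), function(i) {
    idx <- (segments_bed$start[i] + 1L):segments_bed$end[i]
    keep <- idx[!masked[idx]]
    if (length(keep) == 0L)
      return(data.frame(segment = segments_bed$segment[i],
                        raw_median = NA_real_, copy_number = NA_real_,
                        unmasked_bp = 0L, qc_pass = FALSE))
    md <- median_low(profile$depth[keep])
    data.frame(segment = segments_bed$segment[i], raw_median = md,
               copy_number = md / target, unmasked_bp = length(keep),
               qc_pass = TRUE)
  })
  do.call(rbind, res)
}

#' Filter samples on minimum repeat-segment depth and cohort flags
#'
#' Keeps samples whose raw median depth over the designated QC segment
#' (the smaller active repeat) reaches `min_depth`, and drops samples
#' belonging to excluded cohorts (e.g. carrying a segmental duplication)
#' regardless of depth.
#'
#' @param samples data.frame with at least `sample` and `b_depth` (raw
#'   median depth of the QC segment); an optional logical column `excluded`
#'   marks cohort-level exclusions.
#' @param min_depth inclusive threshold.
#' @return list with `kept` (data.frame subset) and `log` (data.frame of
#'   exclusions and reasons).
#' @export
qc_filter <- function(samples, min_depth = 40) {
  excluded <- if ("excluded" %in% names(samples)) samples$excluded else
    rep(FALSE, nrow(samples))
  low <- samples$b_depth < min_depth
  reason <- ifelse(excluded, "excluded cohort",
                   ifelse(low, sprintf("QC segment depth < %g", min_depth), NA))
  keep <- !excluded & !low
  list(kept = samples[keep, , drop = FALSE],
       log = data.frame(sample = samples$sample[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Scan a normalized depth profile for segmental duplications
#'
#' Slides non-overlapping windows over each segment and reports merged
#' intervals whose mean depth exceeds `fold` times the segment's baseline
#' depth. By default the baseline is the segment's own median, which
#' detects duplications confined to part of a segment; to also detect a
#' duplication spanning a whole segment, supply `baseline` — the expected
#' per-segment depth from an external reference (e.g. cohort medians times
#' the sample's target coverage).
#'
#' @param profile a [depth_profile()].
#' @param segments_bed data.frame `segment`, `start`, `end`.
#' @param window window size in bp.
#' @param fold ratio threshold.
#' @param baseline optional named numeric vector of expected depth per
#'   segment.
#' @return data.frame `segment`, `start`, `end`, `mean_ratio` (merged
#'   anomalous intervals); zero rows when the profile is clean.
#' @export
duplication_scan <- function(profile, segments_bed, window = 1000L,
                             fold = 1.5, baseline = NULL) {
  out <- list()
  for (i in seq_len(nrow(segments_bed))) {
    idx <- (segments_bed$start[i] + 1L):segments_bed$end[i]
    segd <- profile$depth[idx]
    md <- if (!is.null(baseline)) baseline[[segments_bed$segment[i]]]
    else median_low(segd)
    if (is.na(md) || md == 0) next
    nb <- length(segd) %/% window
    if (nb == 0L) next
    starts <- (seq_len(nb) - 1L) * window
    ratios <- vapply(seq_len(nb), function(w)
      mean(segd[(starts[w] + 1L):min(starts[w] + window, length(segd))]) / md,
      0)
    hot <- ratios > fold
    if (!any(hot)) next
    iv <- cbind(segments_bed$start[i] + starts[hot],
                segments_bed$start[i] + pmin(starts[hot] + window,
                                             length(segd)))
    m <- merge_intervals(iv)
    for (r in seq_len(nrow(m)))
      out[[length(out) + 1L]] <- data.frame(
        segment = segments_bed$segment[i], start = m[r, 1L], end = m[r, 2L],
        mean_ratio = mean(profile$depth[(m[r, 1L] + 1L):m[r, 2L]]) / md,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(segment = character(), start = integer(),
                      end = integer(), mean_ratio = numeric()))
  do.call(rbind, out)
}
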