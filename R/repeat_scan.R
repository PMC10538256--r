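## Detection of direct and inverted repeat pairs by ungapped diagonal
## scanning: candidate diagonals come from shared k-mer seeds (or all
## diagonals in exhaustive mode), and on each diagonal the longest
## identity-constrained, match-ended windows are extracted.

## Ungapped HSPs on one match vector: seeds are maximal exact runs of at
## least `word` matches; each seed is extended in both directions under a
## match/mismatch score of +1 / -mu with an X-drop stop, then trimmed back
## to the maximum-score ends. mu = min_id/(1-min_id) makes a segment score
## non-negatively exactly when its identity reaches min_id. Windows are
## emitted left to right; a seed already inside an emitted window is
## skipped. Returns matrix (start, end, matches), 1-based inclusive.
extend_hsps <- function(m, min_id, min_len, word, xdrop = 100) {
  n <- length(m)
  r <- rle(m)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  seeds <- which(r$values & r$lengths >= word)
  if (length(seeds) == 0L) return(matrix(integer(0), ncol = 3))
  mu <- min_id / (1 - min_id)
  s <- ifelse(m, 1, -mu)
  out <- NULL
  last_end <- 0L
  for (si in seeds) {
    a <- run_start[si]; b <- run_end[si]
    if (b <= last_end) next
    ## extend right from b
    R <- b
    if (b < n) {
      cum <- 0; maxv <- 0
      for (t in (b + 1L):n) {
        cum <- cum + s[t]
        if (cum > maxv) { maxv <- cum; R <- t }
        if (cum < maxv - xdrop) break
      }
    }
    ## extend left from a
    L <- a
    if (a > 1L) {
      cum <- 0; maxv <- 0
      for (t in (a - 1L):1L) {
        cum <- cum + s[t]
        if (cum > maxv) { maxv <- cum; L <- t }
        if (cum < maxv - xdrop) break
      }
    }
    len <- R - L + 1L
    matches <- sum(m[L:R])
    if (len >= min_len && matches / len >= min_id - 1e-9)
      out <- rbind(out, c(L, R, as.integer(matches)))
    last_end <- max(last_end, R)
  }
  if (is.null(out)) return(matrix(integer(0), ncol = 3))
  unique(out)
}

## Scan one diagonal: x1 vs x2 (integer-encoded), aligned with offset so
## that x2 index = x1 index + off.
scan_diagonal <- function(x1, x2, off, min_id, min_len, word, xdrop = 100) {
  n1 <- length(x1); n2 <- length(x2)
  i_start <- max(1L, 1L - off)
  i_end <- min(n1, n2 - off)
  if (i_end - i_start + 1L < min_len) return(NULL)
  idx <- i_start:i_end
  m <- x1[idx] == x2[idx + off]
  m[is.na(m)] <- FALSE                    # ambiguous bases never match
  w <- extend_hsps(m, min_id, min_len, word, xdrop)
  if (nrow(w) == 0L) return(NULL)
  cbind(start1 = w[, 1L] + i_start - 1L,
        end1 = w[, 2L] + i_start - 1L,
        matches = w[, 3L])
}

## Candidate diagonals from shared k-mers of two integer-encoded sequences.
seed_diagonals <- function(x1, x2, k, min_hits = 1L, max_code_freq = 200L) {
  c1 <- kmer_codes(x1, k); c2 <- kmer_codes(x2, k)
  d1 <- data.table::data.table(code = c1, p1 = seq_along(c1))[!is.na(code)]
  d2 <- data.table::data.table(code = c2, p2 = seq_along(c2))[!is.na(code)]
  ## drop hyper-frequent k-mers to bound the join
  freq <- d2[, .N, by = "code"]
  d2 <- d2[freq[freq$N <= max_code_freq], on = "code", nomatch = NULL]
  hits <- d1[d2, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(integer(0))
  hits[, "off" := hits$p2 - hits$p1]
  tab <- hits[, .N, by = "off"]
  sort(tab$off[tab$N >= min_hits])
}

#' Find direct and inverted repeat pairs in a genome sequence
#'
#' Self-comparison of a genome under an ungapped diagonal model: candidate
#' diagonals are selected by shared k-mer seeds (`method = "seed"`) or
#' scanned exhaustively (`method = "exhaustive"`, the independent reference
#' path for small inputs), and on each diagonal maximal match-ended windows
#' with identity at or above the threshold are reported. Self-hits and
#' mirror duplicates are removed; copies must be separated by at least
#' `min_separation` bp.
#'
#' @param sequence genome as a character string (or `DNAString`).
#' @param min_len minimum repeat unit length in bp.
#' @param min_identity minimum fraction of matching positions.
#' @param min_separation minimum gap in bp between the two copies
#'   (`copy2_start - copy1_end`).
#' @param circular scan the circular genome via a doubled linearization
#'   with deduplication of wrapped hits.
#' @param method `"seed"` (k-mer selected diagonals) or `"exhaustive"`
#'   (every diagonal; quadratic, for small sequences).
#' @param seed_len k-mer length for diagonal selection.
#' @param min_seed_hits minimum seed count for a diagonal to be scanned;
#'   raise above 1 to speed up large genomes at some sensitivity cost.
#' @param word_size minimum exact-match run length used to seed ungapped
#'   extension on a diagonal (lower it together with `min_len` for highly
#'   diverged repeats).
#' @param xdrop score drop-off at which extension stops (match +1, mismatch
#'   `-min_identity/(1-min_identity)`).
#' @return data.frame with columns `copy1_start`, `copy1_end`,
#'   `copy2_start`, `copy2_end` (0-based half-open), `orientation`
#'   (`"direct"`/`"inverted"`), `length`, `identity`, `nested_in_active`
#'   (initialized `FALSE`), ordered by copy1 then copy2 start.
#' @export
find_repeat_pairs <- function(sequence, min_len = 50L, min_identity = 0.80,
                              min_separation = 2000L, circular = FALSE,
                              method = c("seed", "exhaustive"),
                              seed_len = 12L, min_seed_hits = 1L,
                              word_size = 11L, xdrop = 100) {
  method <- match.arg(method)
  word <- min(word_size, min_len)
  seq_chr <- as.character(sequence)
  n <- nchar(seq_chr)
  if (n <= 2L * min_len + min_separation) {
    warning("sequence too short for a repeat pair under these thresholds")
    return(empty_repeat_pairs())
  }
  work <- if (circular) paste0(seq_chr, seq_chr) else seq_chr
  xi <- dna_to_int(work)
  rc <- dna_to_int(revcomp_chr(work))

  rows <- list()
  collect <- function(s1, e1, s2, e2, orientation, matches) {
    len <- e1 - s1 + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      copy1_start = s1 - 1L, copy1_end = e1,
      copy2_start = s2 - 1L, copy2_end = e2,
      orientation = orientation, length = len,
      identity = matches / len, stringsAsFactors = FALSE)
  }

  ## ---- direct: seq vs itself, offsets > 0 --------------------------------
  offs <- if (method == "exhaustive") seq_len(length(xi) - min_len)
  else seed_diagonals(xi, xi, k = min(seed_len, min_len),
                      min_hits = min_seed_hits)
  offs <- offs[offs >= min_len + min_separation]   # gap >= min_separation
  for (off in offs) {
    w <- scan_diagonal(xi, xi, off, min_identity, min_len, word, xdrop)
    if (is.null(w)) next
    for (r in seq_len(nrow(w))) {
      s1 <- w[r, 1L]; e1 <- w[r, 2L]
      s2 <- s1 + off; e2 <- e1 + off
      if (s2 - 1L - e1 < min_separation) next
      if (e1 - s1 + 1L > n) next
      if (circular && s1 > n) next               # wrapped duplicate
      collect(s1, e1, s2, e2, "direct", w[r, 3L])
    }
  }

  ## ---- inverted: seq vs its reverse complement --------------------------
  nw <- length(xi)
  offs <- if (method == "exhaustive") seq(-(nw - min_len), nw - min_len)
  else seed_diagonals(xi, rc, k = min(seed_len, min_len),
                      min_hits = min_seed_hits)
  for (off in offs) {
    w <- scan_diagonal(xi, rc, off, min_identity, min_len, word, xdrop)
    if (is.null(w)) next
    for (r in seq_len(nrow(w))) {
      s1 <- w[r, 1L]; e1 <- w[r, 2L]
      ## rc position p maps to forward position nw - p + 1
      s2 <- nw - (e1 + off) + 1L
      e2 <- nw - (s1 + off) + 1L
      if (e1 - s1 + 1L > n) next
      ## mirror dedup: keep copy1 left of copy2
      if (s2 < s1) next
      if (s2 - 1L - e1 < min_separation) next
      if (circular && s1 > n) next
      collect(s1, e1, s2, e2, "inverted", w[r, 3L])
    }
  }

  if (length(rows) == 0L) return(empty_repeat_pairs())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (circular) {
    ## map copies back to [0, n); an end past n denotes a wrap past the
    ## origin of the circular reference
    out$copy1_start <- out$copy1_start %% n
    out$copy2_start <- out$copy2_start %% n
    out$copy1_end <- out$copy1_start + out$length
    out$copy2_end <- out$copy2_start + out$length
    ## canonical copy order
    swap <- out$copy2_start < out$copy1_start
    if (any(swap)) {
      tmp <- out[swap, c("copy1_start", "copy1_end")]
      out[swap, c("copy1_start", "copy1_end")] <-
        out[swap, c("copy2_start", "copy2_end")]
      out[swap, c("copy2_start", "copy2_end")] <- tmp
    }
    out <- unique(out)
    ## prune fragments of a longer pair split at the linearization break:
    ## a pair is dropped when both of its copies are circularly contained
    ## in the copies of a longer pair
    contained <- function(ps, pl, qs, ql) ((ps - qs) %% n) + pl <= ql
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(nrow(out))) {
        if (i == j || !keep[j] || out$length[j] <= out$length[i]) next
        if (out$orientation[i] != out$orientation[j]) next
        c11 <- contained(out$copy1_start[i], out$length[i],
                         out$copy1_start[j], out$length[j])
        c22 <- contained(out$copy2_start[i], out$length[i],
                         out$copy2_start[j], out$length[j])
        c12 <- contained(out$copy1_start[i], out$length[i],
                         out$copy2_start[j], out$length[j])
        c21 <- contained(out$copy2_start[i], out$length[i],
                         out$copy1_start[j], out$length[j])
        if ((c11 && c22) || (c12 && c21)) { keep[i] <- FALSE; break }
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- unique(out)
  out$nested_in_active <- FALSE
  out <- out[order(out$copy1_start, out$copy2_start, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_repeat_pairs <- function() {
  data.frame(copy1_start = integer(), copy1_end = integer(),
             copy2_start = integer(), copy2_end = integer(),
             orientation = character(), length = integer(),
             identity = numeric(), nested_in_active = logical())
}

#' Flag repeat pairs nested inside active repeat copies
#'
#' A pair is flagged when either of its copies lies entirely within a copy
#' of an active pair, because reads crossing it reflect the host repeat's
#' recombination signal rather than its own.
#'
#' @param pairs data.frame from [find_repeat_pairs()].
#' @param active_pairs data.frame of the recombinationally active pairs
#'   (same columns), on the same reference.
#' @return `pairs` with `nested_in_active` set.
#' @export
flag_nested <- function(pairs, active_pairs) {
  if (nrow(pairs) == 0L || is.null(active_pairs) || nrow(active_pairs) == 0L) {
    if (nrow(pairs) > 0L) pairs$nested_in_active <- FALSE
    return(pairs)
  }
  host <- rbind(
    cbind(start = active_pairs$copy1_start, end = active_pairs$copy1_end),
    cbind(start = active_pairs$copy2_start, end = active_pairs$copy2_end)
  )
  contained <- function(s, e) {
    any(host[, "start"] <= s & e <= host[, "end"])
  }
  pairs$nested_in_active <- vapply(seq_len(nrow(pairs)), function(i) {
    contained(pairs$copy1_start[i], pairs$copy1_end[i]) ||
      contained(pairs$copy2_start[i], pairs$copy2_end[i])
  }, TRUE)
  pairs
}
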