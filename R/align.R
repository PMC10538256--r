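## Lightweight anchor-and-extend read matcher used by the recombination
## activity estimator and the segment-path projector. Reads are located on a
## reference by shared k-mer anchors voting for a diagonal; the best local
## ungapped segment on that diagonal (match +1, mismatch -mu) gives the
## alignment span and identity. Adequate for substitution-dominated errors
## at the >= 80% identity contracts used throughout; not a general aligner.

#' Precompute a k-mer index of a reference sequence
#'
#' @param seq reference sequence (character).
#' @param k k-mer length (<= 26).
#' @param max_code_freq k-mers occurring more often than this in the
#'   reference are dropped from the index (repeat saturation guard).
#' @return list with the integer-encoded sequence and a keyed k-mer table;
#'   pass to [match_read()] to avoid re-indexing per read.
#' @export
seq_index <- function(seq, k = 13L, max_code_freq = 100L) {
  x <- dna_to_int(as.character(seq))
  codes <- kmer_codes(x, k)
  dt <- data.table::data.table(code = codes, pos = seq_along(codes))
  dt <- dt[!is.na(dt$code)]
  freq <- dt[, .N, by = "code"]
  dt <- dt[freq[freq$N <= max_code_freq], on = "code", nomatch = NULL]
  data.table::setkeyv(dt, "code")
  list(x = x, dt = dt, k = k)
}

## Best local alignment of an integer-encoded read against an indexed
## reference. Returns NULL or list(ref_start, ref_end (1-based inclusive),
## read_start, read_end, identity, score, n_anchors, offset).
match_diagonal <- function(read_i, index, min_id = 0.80) {
  k <- index$k
  if (length(read_i) < k) return(NULL)
  cr <- kmer_codes(read_i, k)
  dr <- data.table::data.table(code = cr, p1 = seq_along(cr))
  dr <- dr[!is.na(dr$code)]
  hits <- index$dt[dr, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  off <- hits$pos - hits$p1
  tab <- sort(table(off), decreasing = TRUE)
  best_off <- as.integer(names(tab)[1L])
  n_anchor <- as.integer(tab[1L])
  ## ungapped overlap of read on reference at this offset
  nr <- length(read_i); nf <- length(index$x)
  i_start <- max(1L, 1L - best_off)
  i_end <- min(nr, nf - best_off)
  if (i_end < i_start) return(NULL)
  idx <- i_start:i_end
  m <- read_i[idx] == index$x[idx + best_off]
  m[is.na(m)] <- FALSE
  mu <- min_id / (1 - min_id)
  best <- kadane_segment(ifelse(m, 1, -mu))
  if (is.null(best)) return(NULL)
  a <- idx[best[1L]]; b <- idx[best[2L]]
  seg_m <- m[best[1L]:best[2L]]
  list(ref_start = a + best_off, ref_end = b + best_off,
       read_start = a, read_end = b,
       identity = sum(seg_m) / length(seg_m),
       score = best[3L], n_anchors = n_anchor, offset = best_off)
}

## Maximum-sum contiguous segment (vectorized Kadane): the segment ends at
## the first position attaining the global maximum of C[t] - min(C[0..t-1])
## and starts just after the earliest prefix minimum before it.
kadane_segment <- function(s) {
  C <- cumsum(s)
  pre <- cummin(c(0, C[-length(C)]))
  M <- C - pre
  t <- which.max(M)
  if (M[t] <= 0) return(NULL)
  i <- match(pre[t], c(0, C)) # earliest prefix index with the minimum
  c(i, t, M[t])
}

## Match a read (character) against an indexed reference, trying both
## strands; returns the better match annotated with strand, or NULL.
match_read <- function(read, index, min_id = 0.80) {
  rd_f <- dna_to_int(read)
  rd_r <- rev(3L - rd_f)  # reverse complement in 0..3 encoding
  mf <- match_diagonal(rd_f, index, min_id = min_id)
  mr <- match_diagonal(rd_r, index, min_id = min_id)
  if (is.null(mf) && is.null(mr)) return(NULL)
  pick_r <- is.null(mf) || (!is.null(mr) && mr$score > mf$score)
  out <- if (pick_r) mr else mf
  out$strand <- if (pick_r) "-" else "+"
  out
}
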