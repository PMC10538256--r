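## Shared test fixtures and independent brute-force oracles.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

mutate_dna <- function(x, rate) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    ab <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(ab, b), 1L), "")
  }
  paste(v, collapse = "")
}

## Toy graph: one repeat R with two copies interleaved with arcs x and y
## (master circle R-x-R-y plus subcircles R-x and R-y).
toy_rxry_graph <- function() {
  segs <- segment_table(c("R", "x", "y"), c(100L, 400L, 300L),
                        is_repeat = c(TRUE, FALSE, FALSE),
                        repeat_name = c("RepT", NA, NA))
  build_segment_graph(segs, c("R>x", "x>R", "R>y", "y>R"))
}

## Random small segment multigraph for enumeration property tests.
random_graph <- function(n_seg = sample(2:5, 1), n_jn = sample(3:8, 1)) {
  ids <- letters[seq_len(n_seg)]
  segs <- segment_table(ids, sample(50:500, n_seg, replace = TRUE),
                        is_repeat = FALSE, repeat_name = NA)
  os <- as.vector(outer(ids, c("+", "-"), paste0))
  left <- sample(os, n_jn, replace = TRUE)
  right <- sample(os, n_jn, replace = TRUE)
  build_segment_graph(segs, data.frame(left = left, right = right))
}

## ---- independent isoform-enumeration oracle ------------------------------
## For every subset of junctions, search (by naive arrangement DFS) for a
## closed walk using each subset junction exactly once; collect canonical
## signatures. Completely separate search strategy from the package's
## walk-growing enumeration.
oracle_enumerate_signatures <- function(graph) {
  j <- graph$junctions
  nj <- nrow(j)
  ## directed usable transitions per canonical key
  trans <- function(key) {
    row <- j[j$key == key, ]
    list(c(row$left, row$right),
         c(mitoforms::os_flip(row$right), mitoforms::os_flip(row$left)))
  }
  found <- character(0)
  for (bits in seq_len(2^nj) - 1L) {
    subset <- j$key[bitwAnd(bits, 2^(seq_len(nj) - 1L)) > 0]
    if (length(subset) == 0L) next
    ## collect every closed arrangement of the subset (they can be
    ## cyclically distinct); each must traverse the first junction, so
    ## anchoring the chain there fixes the rotation
    for (d in trans(subset[1L])) {
      walks <- oracle_arrangements(d, setdiff(subset, subset[1L]), trans)
      for (walk in walks)
        found <- c(found, paste(mitoforms::canonical_walk(walk),
                                collapse = ","))
    }
  }
  unname(sort(unique(found), method = "radix"))
}

## All completions of a chain into a closed walk using every remaining
## junction exactly once. Chain state: vector of oriented segments.
oracle_arrangements <- function(start_dir, remaining, trans) {
  acc <- list()
  recurse <- function(chain, remaining) {
    if (length(remaining) == 0L) {
      if (identical(chain[1L], chain[length(chain)]))
        acc[[length(acc) + 1L]] <<- chain[-length(chain)]
      return(invisible(NULL))
    }
    for (key in remaining) {
      for (d in trans(key)) {
        if (identical(d[1L], chain[length(chain)]))
          recurse(c(chain, d[2L]), setdiff(remaining, key))
      }
    }
  }
  recurse(c(start_dir[1L], start_dir[2L]), remaining)
  acc
}

enum_signatures <- function(isoforms) {
  unname(sort(vapply(isoforms, function(i)
    paste(mitoforms::canonical_walk(i$walk), collapse = ","), ""),
    method = "radix"))
}

## ---- independent repeat-scan oracle --------------------------------------
## Quadratic scan of every diagonal with plainly-coded run finding and
## X-drop extension, mirroring the documented HSP semantics of
## find_repeat_pairs() without sharing its code.
oracle_repeat_pairs <- function(seq_chr, min_len = 20L, min_identity = 0.8,
                                min_separation = 50L, word = 4L,
                                xdrop = 100) {
  enc <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  x <- enc(seq_chr)
  xr <- enc(rc(seq_chr))
  n <- length(x)
  mu <- min_identity / (1 - min_identity)
  hsps_on <- function(m) {
    ## exact runs >= word found by position scanning
    out <- NULL
    runs <- NULL
    i <- 1L
    while (i <= length(m)) {
      if (m[i]) {
        j <- i
        while (j < length(m) && m[j + 1L]) j <- j + 1L
        if (j - i + 1L >= word) runs <- rbind(runs, c(i, j))
        i <- j + 1L
      } else i <- i + 1L
    }
    last_end <- 0L
    for (r in seq_len(NROW(runs))) {
      a <- runs[r, 1L]; b <- runs[r, 2L]
      if (b <= last_end) next
      R <- b; cum <- 0; mx <- 0
      t <- b + 1L
      while (t <= length(m)) {
        cum <- cum + if (m[t]) 1 else -mu
        if (cum > mx) { mx <- cum; R <- t }
        if (cum < mx - xdrop) break
        t <- t + 1L
      }
      L <- a; cum <- 0; mx <- 0
      t <- a - 1L
      while (t >= 1L) {
        cum <- cum + if (m[t]) 1 else -mu
        if (cum > mx) { mx <- cum; L <- t }
        if (cum < mx - xdrop) break
        t <- t - 1L
      }
      len <- R - L + 1L
      ident <- sum(m[L:R]) / len
      if (len >= min_len && ident >= min_identity - 1e-9)
        out <- rbind(out, c(L, R, sum(m[L:R])))
      last_end <- max(last_end, R)
    }
    if (is.null(out)) NULL else unique(out)
  }
  rows <- NULL
  for (off in seq_len(n - min_len)) {
    idx <- 1:(n - off)
    m <- x[idx] == x[idx + off]
    w <- hsps_on(m)
    for (r in seq_len(NROW(w))) {
      s1 <- w[r, 1L]; e1 <- w[r, 2L]
      if ((s1 + off) - 1L - e1 < min_separation) next
      rows <- rbind(rows, data.frame(
        copy1_start = s1 - 1L, copy1_end = e1,
        copy2_start = s1 + off - 1L, copy2_end = e1 + off,
        orientation = "direct", length = e1 - s1 + 1L,
        identity = w[r, 3L] / (e1 - s1 + 1L)))
    }
  }
  for (off in seq(-(n - min_len), n - min_len)) {
    i_start <- max(1L, 1L - off); i_end <- min(n, n - off)
    if (i_end - i_start + 1L < min_len) next
    idx <- i_start:i_end
    m <- x[idx] == xr[idx + off]
    w <- hsps_on(m)
    for (r in seq_len(NROW(w))) {
      s1 <- idx[1L] + w[r, 1L] - 1L
      e1 <- idx[1L] + w[r, 2L] - 1L
      s2 <- n - (e1 + off) + 1L
      e2 <- n - (s1 + off) + 1L
      if (s2 < s1) next
      if (s2 - 1L - e1 < min_separation) next
      rows <- rbind(rows, data.frame(
        copy1_start = s1 - 1L, copy1_end = e1,
        copy2_start = s2 - 1L, copy2_end = e2,
        orientation = "inverted", length = e1 - s1 + 1L,
        identity = w[r, 3L] / (e1 - s1 + 1L)))
    }
  }
  if (is.null(rows)) return(rows)
  rows <- unique(rows)
  rows[order(rows$copy1_start, rows$copy2_start, rows$orientation), ,
       drop = FALSE]
}

## Plant a repeat with explicit non-matching boundary bases so that
## detected coordinates are exact.
plant_exact_pair <- function(left, unit, middle, second_unit, right) {
  force_base <- function(s, pos, base) {
    substr(s, pos, pos) <- base
    s
  }
  seqn <- paste0(left, unit, middle, second_unit, right)
  n1 <- nchar(left); nu <- nchar(unit); nm <- nchar(middle)
  ## bases flanking the copies chosen so that neither direct extension
  ## (A vs C) nor inverted extension (A vs revcomp(C) = G) can match
  seqn <- force_base(seqn, n1, "A")
  seqn <- force_base(seqn, n1 + nu + 1L, "A")
  seqn <- force_base(seqn, n1 + nu + nm, "C")
  seqn <- force_base(seqn, n1 + nu + nm + nchar(second_unit) + 1L, "C")
  ## and the matching positions of the other copy's context must differ
  list(seq = seqn,
       copy1 = c(n1, n1 + nu),                    # 0-based half-open
       copy2 = c(n1 + nu + nm, n1 + nu + nm + nchar(second_unit)))
}
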