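## Segment decomposition of an assembly graph at active repeat copies, and
## enumeration of all junction-simple circular isoforms with their
## recombination reaction network.

#' Cut assembly-graph edges into minimal genome segments
#'
#' Each edge of the assembly graph is cut at the boundaries of every active
#' repeat copy it contains. All copies of one repeat collapse to a single
#' segment id, so a repeat contributes one segment no matter how many genomic
#' copies exist. Junctions are recorded between adjacent pieces within an
#' edge and across branch points: at a node, the last piece of every incoming
#' edge joins the first piece of every outgoing edge.
#'
#' @param edges data.frame with columns `edge_id`, `from`, `to`, `length`
#'   (bp); `from`/`to` are node labels (an edge with `from == to` closes a
#'   circle on its own).
#' @param repeat_copies data.frame with columns `edge_id`, `start`, `end`
#'   (0-based half-open within the edge) and `repeat_name`; may have zero
#'   rows. Copies within one edge must not overlap.
#' @param piece_labels optional character vector used (in order of
#'   generation) to label non-repeat pieces; defaults to s1, s2, ...
#' @return a list: `graph` (a [build_segment_graph()] object) and `pieces`
#'   (data.frame mapping each genomic piece to edge coordinates and its
#'   segment id).
#' @export
segment_genome <- function(edges, repeat_copies = NULL, piece_labels = NULL) {
  if (is.null(repeat_copies))
    repeat_copies <- data.frame(edge_id = character(), start = integer(),
                                end = integer(), repeat_name = character())
  pieces <- list()
  next_label <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      if (!is.null(piece_labels) && k <= length(piece_labels)) piece_labels[k]
      else paste0("s", k)
    }
  })
  rep_ids <- list()  # repeat_name -> segment id
  for (ei in seq_len(nrow(edges))) {
    eid <- edges$edge_id[ei]
    elen <- edges$length[ei]
    rc <- repeat_copies[repeat_copies$edge_id == eid, , drop = FALSE]
    rc <- rc[order(rc$start), , drop = FALSE]
    if (nrow(rc) > 1L && any(rc$start[-1L] < rc$end[-nrow(rc)]))
      stop("overlapping repeat copies on edge ", eid, " are not supported")
    if (nrow(rc) > 0L && (any(rc$start < 0L) || any(rc$end > elen)))
      stop("repeat copy outside edge ", eid)
    cuts <- sort(unique(c(0L, rc$start, rc$end, elen)))
    for (pi in seq_len(length(cuts) - 1L)) {
      s <- cuts[pi]; e <- cuts[pi + 1L]
      hit <- which(rc$start == s & rc$end == e)
      if (length(hit) == 1L) {
        rn <- rc$repeat_name[hit]
        if (is.null(rep_ids[[rn]])) rep_ids[[rn]] <- next_label()
        seg_id <- rep_ids[[rn]]
        is_rep <- TRUE
        rep_name <- rn
      } else {
        seg_id <- next_label()
        is_rep <- FALSE
        rep_name <- NA_character_
      }
      pieces[[length(pieces) + 1L]] <- data.frame(
        edge_id = eid, start = s, end = e, segment = seg_id,
        is_repeat = is_rep, repeat_name = rep_name, stringsAsFactors = FALSE)
    }
  }
  pieces <- do.call(rbind, pieces)

  ## segment table: one row per distinct segment id
  first <- !duplicated(pieces$segment)
  segs <- segment_table(
    id = pieces$segment[first],
    length = pieces$end[first] - pieces$start[first],
    is_repeat = pieces$is_repeat[first],
    repeat_name = pieces$repeat_name[first]
  )
  copies <- table(pieces$segment)
  repeat_copies_n <- setNames(as.integer(copies[segs$id]), segs$id)

  ## junctions: consecutive pieces within an edge, plus node adjacencies
  jl <- character(0); jr <- character(0)
  for (eid in unique(pieces$edge_id)) {
    p <- pieces[pieces$edge_id == eid, , drop = FALSE]
    if (nrow(p) > 1L) {
      jl <- c(jl, paste0(p$segment[-nrow(p)], "+"))
      jr <- c(jr, paste0(p$segment[-1L], "+"))
    }
  }
  for (node in unique(c(edges$from, edges$to))) {
    incoming <- edges$edge_id[edges$to == node]
    outgoing <- edges$edge_id[edges$from == node]
    for (ein in incoming) for (eout in outgoing) {
      pin <- pieces[pieces$edge_id == ein, , drop = FALSE]
      pout <- pieces[pieces$edge_id == eout, , drop = FALSE]
      jl <- c(jl, paste0(pin$segment[nrow(pin)], "+"))
      jr <- c(jr, paste0(pout$segment[1L], "+"))
    }
  }
  graph <- build_segment_graph(segs,
                               data.frame(left = jl, right = jr),
                               repeat_copies = repeat_copies_n)
  list(graph = graph, pieces = pieces)
}

## ---- enumeration ---------------------------------------------------------

## Directed traversal table: each canonical junction can be crossed in two
## directions (as written, or strand-flipped). Rows: from, to, key.
junction_transitions <- function(graph) {
  j <- graph$junctions
  rbind(
    data.frame(from = j$left, to = j$right, key = j$key,
               stringsAsFactors = FALSE),
    data.frame(from = os_flip(j$right), to = os_flip(j$left), key = j$key,
               stringsAsFactors = FALSE)
  )
}

#' Enumerate all junction-simple circular isoforms
#'
#' A circular isoform is a closed walk over oriented segments in which every
#' consecutive pair is a junction of the graph and no junction is crossed
#' more than once. This is the weakest combinatorial rule that reproduces
#' the published isoform set on the nine-segment fixture while excluding
#' dimeric and larger circles that reuse a junction. A circle and its
#' reverse complement count as a single isoform; the stored representative
#' is the lexicographically least rotation over both strands.
#'
#' @param graph a [build_segment_graph()] object.
#' @return a list of [isoform()] objects (provenance `"enumerated"`) named
#'   `cir1`, `cir2`, ... in canonical-walk order; empty if the graph carries
#'   no cycle.
#' @export
enumerate_isoforms <- function(graph) {
  tr <- junction_transitions(graph)
  found <- new.env(parent = emptyenv())
  starts <- unique(tr$from)
  for (start in starts) {
    walk_env <- new.env(parent = emptyenv())
    dfs <- function(walk, used_keys) {
      cur <- walk[length(walk)]
      cand <- which(tr$from == cur & !(tr$key %in% used_keys))
      for (ci in cand) {
        nxt <- tr$to[ci]
        key <- tr$key[ci]
        if (nxt == walk[1L]) {
          sig <- walk_signature(walk)
          if (is.null(found[[sig]]))
            found[[sig]] <- canonical_walk(walk)
        }
        ## continue even after closing: longer circles may pass through the
        ## start oriented segment more than once
        dfs(c(walk, nxt), c(used_keys, key))
      }
    }
    dfs(start, character(0))
  }
  sigs <- sort(ls(found), method = "radix")
  out <- lapply(seq_along(sigs), function(k)
    isoform(paste0("cir", k), found[[sigs[k]]], graph = graph,
            provenance = "enumerated"))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Classify circular isoforms into master circles and subgenomes
#'
#' A master circle traverses some repeat segment at least twice (so
#' intramolecular recombination between the two copies can split it); a
#' subgenome contains every repeat at most once.
#'
#' @param isoforms list of [isoform()] objects.
#' @param graph the governing segment graph.
#' @return list with character vectors `masters` and `subgenomes` (isoform
#'   names).
#' @export
classify_isoforms <- function(isoforms, graph) {
  rep_ids <- graph$segments$id[graph$segments$is_repeat]
  is_master <- vapply(isoforms, function(iso) {
    tab <- table(os_id(iso$walk))
    any(names(tab) %in% rep_ids & tab >= 2L)
  }, TRUE)
  nms <- vapply(isoforms, `[[`, "", "name")
  list(masters = nms[is_master], subgenomes = nms[!is_master])
}

## Fission products of a master at two occurrences of one repeat segment.
## Walk [R, X..., R, Y...] splits into [R, X...] and [R, Y...].
fission_products <- function(walk, i1, i2) {
  n <- length(walk)
  p1 <- walk[i1:(i2 - 1L)]
  p2 <- walk[c(i2:n, seq_len(i1 - 1L))]
  list(p1, p2)
}

#' Recombination reaction network of an isoform pool
#'
#' For every master circle and every repeat segment it traverses twice (in
#' the same orientation), computes the two fission products of
#' intramolecular recombination between the two repeat copies and matches
#' them against the enumerated pool. Fusion is the reverse direction of the
#' same reaction. Products not present in the pool are reported as
#' `in_pool = FALSE` (larger/irregular circles).
#'
#' @param isoforms list of [isoform()] objects (the enumerated pool).
#' @param graph the governing segment graph.
#' @return data.frame with columns `master`, `repeat_id`, `repeat_name`,
#'   `product1`, `product2`, `in_pool`.
#' @export
reaction_network <- function(isoforms, graph) {
  sig2name <- setNames(
    vapply(isoforms, `[[`, "", "name"),
    vapply(isoforms, function(i) walk_signature(i$walk), "")
  )
  rep_ids <- graph$segments$id[graph$segments$is_repeat]
  rows <- list()
  for (iso in isoforms) {
    walk <- iso$walk
    ids <- os_id(walk)
    for (rid in rep_ids) {
      occ <- which(ids == rid)
      if (length(occ) < 2L) next
      for (a in seq_len(length(occ) - 1L)) for (b in (a + 1L):length(occ)) {
        i1 <- occ[a]; i2 <- occ[b]
        ## direct-repeat recombination requires equal orientation
        if (os_strand(walk[i1]) != os_strand(walk[i2])) next
        pr <- fission_products(walk, i1, i2)
        s1 <- walk_signature(pr[[1]]); s2 <- walk_signature(pr[[2]])
        nm1 <- if (!is.na(sig2name[s1])) unname(sig2name[s1]) else paste0("<", s1, ">")
        nm2 <- if (!is.na(sig2name[s2])) unname(sig2name[s2]) else paste0("<", s2, ">")
        nm <- sort(c(nm1, nm2), method = "radix")
        rows[[length(rows) + 1L]] <- data.frame(
          master = iso$name,
          repeat_id = rid,
          repeat_name = graph$segments$repeat_name[match(rid, graph$segments$id)],
          product1 = nm[1L], product2 = nm[2L],
          in_pool = s1 %in% names(sig2name) && s2 %in% names(sig2name),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(master = character(), repeat_id = character(),
                      repeat_name = character(), product1 = character(),
                      product2 = character(), in_pool = logical()))
  out <- do.call(rbind, rows)
  unique(out)
}

#' Closure of an isoform set under its recombination reactions
#'
#' Repeatedly applies every fission (master into two products) and fusion
#' (two circles sharing a repeat into one) reaction starting from a seed set
#' and returns all junction-simple circles reached.
#'
#' @param seed list of [isoform()] objects to start from.
#' @param graph the governing segment graph.
#' @param max_iter safety bound on fixed-point iterations.
#' @return list of isoforms (canonical walks, provenance `"enumerated"`).
#' @export
reaction_closure <- function(seed, graph, max_iter = 20L) {
  pool <- new.env(parent = emptyenv())
  add_walk <- function(walk) {
    ## keep only junction-simple circles valid in the graph
    ok <- tryCatch({
      isoform("tmp", walk, graph = graph)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) return(FALSE)
    sig <- walk_signature(walk)
    if (is.null(pool[[sig]])) {
      pool[[sig]] <- canonical_walk(walk)
      TRUE
    } else FALSE
  }
  for (iso in seed) add_walk(iso$walk)
  rep_ids <- graph$segments$id[graph$segments$is_repeat]
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    walks <- as.list(pool)
    ## fissions
    for (w in walks) {
      ids <- os_id(w)
      for (rid in rep_ids) {
        occ <- which(ids == rid)
        if (length(occ) < 2L) next
        for (a in seq_len(length(occ) - 1L)) for (b in (a + 1L):length(occ)) {
          if (os_strand(w[occ[a]]) != os_strand(w[occ[b]])) next
          pr <- fission_products(w, occ[a], occ[b])
          changed <- add_walk(pr[[1]]) | changed
          changed <- add_walk(pr[[2]]) | changed
        }
      }
    }
    ## fusions: two circles each containing a repeat once
    walks <- as.list(pool)
    if (length(walks) >= 2L) {
      for (x in seq_len(length(walks) - 1L)) for (y in (x + 1L):length(walks)) {
        for (rid in rep_ids) {
          w1 <- walks[[x]]; w2 <- walks[[y]]
          o1 <- which(os_id(w1) == rid); o2 <- which(os_id(w2) == rid)
          if (length(o1) != 1L || length(o2) != 1L) next
          r1 <- w1[c(o1:length(w1), seq_len(o1 - 1L))]
          r2 <- w2[c(o2:length(w2), seq_len(o2 - 1L))]
          if (os_strand(r1[1L]) != os_strand(r2[1L])) r2 <- rev(os_flip(r2))
          ## after strand fix, rotate r2 to start at the repeat again
          o2b <- which(os_id(r2) == rid)
          r2 <- r2[c(o2b:length(r2), seq_len(o2b - 1L))]
          changed <- add_walk(c(r1, r2)) | changed
        }
      }
    }
    if (!changed) break
  }
  sigs <- sort(ls(pool), method = "radix")
  out <- lapply(seq_along(sigs), function(k)
    isoform(paste0("cl", k), pool[[sigs[k]]], graph = graph,
            provenance = "enumerated"))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
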