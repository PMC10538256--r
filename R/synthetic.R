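## Seeded generators for synthetic genomes, long reads, depth profiles and
## nuclear backgrounds with recorded truth. They emulate the study design the
## package targets: a multipartite mitogenome whose segments are shared
## across circular isoforms, long reads sampled from a weighted isoform pool,
## and short-read depth that scales with segment copy number against a
## diploid nuclear background.

#' Generate a synthetic genome for a segment-graph fixture
#'
#' Draws a random sequence for every unique segment (repeat segments get one
#' sequence, so genomic copies are perfect) and concatenates them into
#' isoform sequences following each walk, reverse-complementing segments
#' traversed on the minus strand. Also lays the unique segments end to end
#' into a linear "graph content" reference used for short-read depth work.
#'
#' @param fixture a fixture list as returned by [zm9_fixture()] (needs
#'   `$graph` and `$isoforms`).
#' @param seed integer seed; identical seeds give identical genomes.
#' @return list with `segments` (named character vector of segment
#'   sequences), `isoform_seqs` (named character vector), `layouts` (per
#'   isoform, data.frame of segment, strand, start, end in isoform
#'   coordinates, 0-based half-open), `reference` (unique segments
#'   concatenated), `segments_bed` (data.frame segment/start/end on the
#'   reference), `fixture`.
#' @export
synth_genome <- function(fixture = zm9_fixture(), seed = 1L) {
  graph <- fixture$graph
  with_seed(seed, {
    seqs <- vapply(seq_len(nrow(graph$segments)), function(i)
      random_dna(graph$segments$length[i]), "")
    names(seqs) <- graph$segments$id
    layouts <- lapply(fixture$isoforms, function(iso) {
      ids <- os_id(iso$walk)
      lens <- segment_length(graph, ids)
      ends <- cumsum(lens)
      data.frame(segment = ids, strand = os_strand(iso$walk),
                 start = ends - lens, end = ends, stringsAsFactors = FALSE)
    })
    iso_seqs <- vapply(fixture$isoforms, function(iso) {
      paste(vapply(seq_along(iso$walk), function(k) {
        s <- seqs[[os_id(iso$walk[k])]]
        if (os_strand(iso$walk[k]) == "-") revcomp_chr(s) else s
      }, ""), collapse = "")
    }, "")
    ends <- cumsum(graph$segments$length)
    list(
      segments = seqs,
      isoform_seqs = iso_seqs,
      layouts = layouts,
      reference = paste(seqs, collapse = ""),
      segments_bed = data.frame(segment = graph$segments$id,
                                start = ends - graph$segments$length,
                                end = ends, stringsAsFactors = FALSE),
      fixture = fixture
    )
  })
}

#' Simulate long reads from a weighted pool of circular isoforms
#'
#' Reads start uniformly on each circular molecule; the molecule is chosen
#' with probability proportional to `weight * molecule length` (a read
#' sampler over a mass-weighted pool). Read lengths follow a normal
#' distribution truncated below and capped at the molecule circumference;
#' reads may wrap around the origin. Substitution errors are applied at
#' `error_rate`; half the reads are emitted reverse-complemented.
#'
#' @param genome a [synth_genome()] result, or any named character vector of
#'   circular molecule sequences.
#' @param weights named non-negative weights over molecules (default: equal
#'   over all molecules in the pool).
#' @param n number of reads.
#' @param length_mean,length_sd read length distribution (bp).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param min_len smallest read emitted.
#' @param circular treat molecules as circles (reads may wrap the origin);
#'   set `FALSE` for linear templates such as flank-composition references.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read, molecule, start (0-based on the forward molecule),
#'   length, strand).
#' @export
simulate_long_reads <- function(genome, weights = NULL, n = 100L,
                                length_mean = 25000, length_sd = 5000,
                                error_rate = 0, seed = 1L, min_len = 200L,
                                circular = TRUE) {
  pool <- if (is.list(genome) && !is.null(genome$isoform_seqs))
    genome$isoform_seqs else unlist(genome)
  if (is.null(weights)) weights <- setNames(rep(1, length(pool)), names(pool))
  weights <- weights[weights > 0]
  pool <- pool[names(weights)]
  if (n == 0L)
    return(list(reads = setNames(character(0), character(0)),
                truth = data.frame(read = character(), molecule = character(),
                                   start = integer(), length = integer(),
                                   strand = character())))
  lens <- nchar(pool)
  with_seed(seed, {
    prob <- weights * lens
    mol <- sample(names(pool), n, replace = TRUE, prob = prob / sum(prob))
    rl <- pmax(min_len, round(rnorm(n, length_mean, length_sd)))
    rl <- pmin(rl, lens[mol])
    start <- if (circular) floor(runif(n) * lens[mol])
    else floor(runif(n) * (lens[mol] - rl + 1L))       # 0-based
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- character(n)
    for (i in seq_len(n)) {
      s <- pool[[mol[i]]]
      dbl <- if (circular) paste0(s, s) else s
      rd <- substr(dbl, start[i] + 1L, start[i] + rl[i])
      if (error_rate > 0) rd <- mutate_seq(rd, error_rate)
      if (strand[i] == "-") rd <- revcomp_chr(rd)
      reads[i] <- rd
    }
    ids <- sprintf("read_%04d", seq_len(n))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read = ids, molecule = mol, start = start,
                            length = rl, strand = strand,
                            stringsAsFactors = FALSE))
  })
}

## Substitution-only error model: each base flips to one of the other three
## with probability `rate`.
mutate_seq <- function(x, rate) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    alphabet <- c("A", "C", "G", "T")
    shift <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(v[hit], alphabet)
    v[hit] <- alphabet[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

#' Simulate short-read depth over the segment reference
#'
#' Per-position depth on the unique-segment reference is Poisson with mean
#' `target * copy number`, where the copy number of a segment is its
#' membership-weighted sum over the isoform stoichiometry `sigma` (a repeat
#' segment receives depth from all of its genomic copies, which map to its
#' single reference representation). Diploid nuclear single-copy gene depths
#' are drawn at mean `2 * target`, matching the convention that the
#' per-replicon target coverage is the mean single-copy gene coverage
#' divided by two.
#'
#' @param sigma named non-negative stoichiometry over isoforms of the
#'   fixture (typically the five subgenomes).
#' @param genome a [synth_genome()] result.
#' @param target per-replicon target coverage (haploid nuclear depth).
#' @param seed integer seed.
#' @param n_genes,gene_len number and length of single-copy nuclear genes.
#' @param copy_boost optional named per-segment additive copy-number excess
#'   (models e.g. overlapping linear molecules inflating one segment).
#' @param dup_region optional `c(start, end)` 0-based interval on the
#'   reference whose depth is multiplied by `dup_fold` (models a segmental
#'   duplication).
#' @param dup_fold fold change applied over `dup_region`.
#' @return list with `profile` (a `depth_profile`), `gene_depths` (per-gene
#'   mean coverages), `copy_truth` (expected copy number per segment) and
#'   `target`.
#' @export
simulate_depth <- function(sigma, genome, target = 50, seed = 1L,
                           n_genes = 67L, gene_len = 3000L,
                           copy_boost = NULL, dup_region = NULL,
                           dup_fold = 2) {
  fixture <- genome$fixture
  graph <- fixture$graph
  isoforms <- fixture$isoforms[names(sigma)]
  m <- membership_matrix(isoforms, graph)
  copy <- as.numeric(m %*% sigma[colnames(m)])
  names(copy) <- rownames(m)
  if (!is.null(copy_boost)) copy[names(copy_boost)] <- copy[names(copy_boost)] + copy_boost
  bed <- genome$segments_bed
  ref_len <- max(bed$end)
  lambda <- numeric(ref_len)
  for (i in seq_len(nrow(bed)))
    lambda[(bed$start[i] + 1L):bed$end[i]] <- target * copy[bed$segment[i]]
  if (!is.null(dup_region))
    lambda[(dup_region[1L] + 1L):dup_region[2L]] <-
      lambda[(dup_region[1L] + 1L):dup_region[2L]] * dup_fold
  with_seed(seed, {
    depth <- rpois(ref_len, lambda)
    gene_depths <- vapply(seq_len(n_genes), function(g)
      mean(rpois(gene_len, 2 * target)), 0)
    list(profile = depth_profile(depth),
         gene_depths = gene_depths,
         copy_truth = copy,
         target = target)
  })
}

#' Plant mitochondrial fragments into a nuclear background (synthetic NUMTs)
#'
#' Copies fragments of the mitochondrial reference into a nuclear background
#' sequence at seeded positions and records the truth mask in mitochondrial
#' coordinates (overlapping fragments merge).
#'
#' @param nuclear_background character string (nuclear sequence).
#' @param mito_reference character string (mitochondrial reference).
#' @param fragments data.frame with `start`, `end` (0-based half-open,
#'   mitochondrial coordinates); zero-length fragments are dropped.
#' @param seed integer seed for insertion positions.
#' @return list with `nuclear` (modified background), `mask_truth` (merged
#'   data.frame start/end in mito coordinates), `insertions` (positions in
#'   the background).
#' @export
plant_numt <- function(nuclear_background, mito_reference, fragments,
                       seed = 1L) {
  fragments <- fragments[fragments$end > fragments$start, , drop = FALSE]
  bg <- nuclear_background
  nb <- nchar(bg)
  ins <- integer(0)
  with_seed(seed, {
    for (i in seq_len(nrow(fragments))) {
      frag <- substr(mito_reference, fragments$start[i] + 1L, fragments$end[i])
      fl <- nchar(frag)
      if (fl > nb) stop("fragment longer than nuclear background")
      pos <- floor(runif(1) * (nb - fl))      # 0-based
      substr(bg, pos + 1L, pos + fl) <- frag
      ins <- c(ins, pos)
    }
    mask <- merge_intervals(cbind(fragments$start, fragments$end))
    list(nuclear = bg,
         mask_truth = data.frame(start = mask[, 1L], end = mask[, 2L]),
         insertions = ins)
  })
}
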