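## End-to-end synthetic workflow: generate a genome for the nine-segment
## architecture, rediscover its repeats, measure recombination activity,
## enumerate and confirm isoforms from long reads, and recover segment copy
## numbers and subgenome stoichiometry from short-read depth.

#' Run the full pipeline on synthetic data
#'
#' Exercises every stage of the package on a seeded synthetic genome built
#' from the nine-segment fixture and returns a structured report:
#'
#' 1. architecture: segment/junction counts, isoform enumeration and
#'    classification, recombination reaction network;
#' 2. repeat scan: direct repeat pairs recovered from the master-circle
#'    sequence;
#' 3. recombination activity at the two planted repeats from a 1:1
#'    parental/recombined long-read mix;
#' 4. junction support and isoform confirmation from a long-read pool over
#'    all isoforms;
#' 5. segment copy number from simulated short-read depth at equal
#'    subgenome stoichiometry (with a planted NUMT masked), and the fixed
#'    and balanced stoichiometry representations.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param target short-read target coverage.
#' @param n_activity_reads reads per repeat for the activity estimate.
#' @param n_support_reads reads for junction support / confirmation.
#' @param read_length_mean,read_length_sd long-read length distribution.
#' @param verbose print a progress line per stage.
#' @return a list report; see the worked example in the package README.
#' @export
run_synthetic_pipeline <- function(seed = 1L, target = 50,
                                   n_activity_reads = 150L,
                                   n_support_reads = 150L,
                                   read_length_mean = 25000,
                                   read_length_sd = 5000,
                                   verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seed <- as.integer(seed)

  ## 1 -- architecture ------------------------------------------------------
  say("building fixture and enumerating isoforms")
  fx <- zm9_fixture()
  enum <- enumerate_isoforms(fx$graph)
  sig_truth <- sort(vapply(fx$isoforms, function(i) walk_signature(i$walk), ""),
                    method = "radix")
  sig_enum <- sort(vapply(enum, function(i) walk_signature(i$walk), ""),
                   method = "radix")
  cls <- classify_isoforms(fx$isoforms, fx$graph)
  reactions <- reaction_network(fx$isoforms, fx$graph)
  architecture <- list(
    n_segments = nrow(fx$graph$segments),
    n_junctions = nrow(fx$graph$junctions),
    n_isoforms = length(enum),
    n_masters = length(cls$masters),
    n_subgenomes = length(cls$subgenomes),
    enumeration_matches_truth = identical(unname(sig_truth),
                                          unname(sig_enum)),
    iso1_length = isoform_length(fx$isoforms$iso1, fx$graph),
    edge_lengths = fx$edge_lengths,
    iso2_note = fx$iso2_note,
    reactions = reactions)

  ## 2 -- repeat scan on the master circle ----------------------------------
  say("scanning iso1 for repeat pairs")
  genome <- synth_genome(fx, seed = seed)
  pairs <- find_repeat_pairs(genome$isoform_seqs[["iso1"]], circular = TRUE,
                             min_seed_hits = 20L)
  repeat_scan <- list(pairs = pairs,
                      n_direct = sum(pairs$orientation == "direct"),
                      n_inverted = sum(pairs$orientation == "inverted"))

  ## 3 -- recombination activity --------------------------------------------
  say("estimating recombination activity")
  rep_segs <- c(Rep1 = "d", Rep2 = "b")
  activity <- lapply(seq_along(rep_segs), function(ri) {
    seg_id <- rep_segs[[ri]]
    pr <- planted_pair(genome, "iso1", seg_id)
    fs <- build_flank_references(genome$isoform_seqs[["iso1"]], pr)
    ## reads drawn 1:1 from parental (M1/M2) and recombined (R1/R2)
    ## molecules, emulating the ~50% activity regime
    rds <- simulate_long_reads(fs$references, n = n_activity_reads,
                               length_mean = nchar(fs$references[["M1"]]),
                               length_sd = 0, error_rate = 0,
                               seed = seed + 17L + ri, circular = FALSE)
    asn <- assign_reads(rds$reads, fs)
    est <- activity_estimate(asn$counts)
    est$n_ambiguous <- asn$n_ambiguous
    est$n_unassigned <- asn$n_unassigned
    est
  })
  names(activity) <- names(rep_segs)

  ## 4 -- long-read junction support and isoform confirmation ---------------
  say("projecting long reads onto segment paths")
  rds <- simulate_long_reads(genome, n = n_support_reads,
                             length_mean = read_length_mean,
                             length_sd = read_length_sd,
                             error_rate = 0, seed = seed + 29L)
  paths <- reads_to_segment_paths(rds$reads, genome)
  jsupport <- junction_support(paths, fx$graph)
  usubs <- unique_subpaths(fx$isoforms, fx$graph)
  confirm <- confirm_isoforms(paths, usubs,
                              max_read_len = max(nchar(rds$reads)))
  read_support <- list(junction_support = jsupport,
                       all_junctions_supported = all(jsupport$support > 0),
                       unique_subpaths = usubs,
                       confirmation = confirm)

  ## 5 -- depth, copy number, stoichiometry ---------------------------------
  say("simulating depth and estimating stoichiometry")
  sigma <- setNames(rep(1, 5), fx$subgenomes)
  sim <- simulate_depth(sigma, genome, target = target, seed = seed + 43L)
  ## plant and mask a NUMT inside segment a
  bed <- genome$segments_bed
  a_row <- bed[bed$segment == "a", ]
  numt_iv <- data.frame(start = a_row$start + 1000L,
                        end = a_row$start + 3000L)
  nuc <- plant_numt(with_seed(seed + 51L, random_dna(20000L)),
                    genome$reference, numt_iv, seed = seed + 51L)
  mask <- mask_homology(genome$reference, nuc$nuclear)
  tc <- target_coverage(sim$gene_depths)
  cn <- segment_copy_number(sim$profile, bed, mask = mask, target = tc)
  copy_vec <- setNames(cn$copy_number, cn$segment)
  est <- fixed_representation(copy_vec)
  depth <- list(target_coverage = tc,
                mask = mask,
                numt_truth = nuc$mask_truth,
                copy_numbers = cn,
                copy_truth = sim$copy_truth,
                recovery_r = stats::cor(copy_vec[names(sim$copy_truth)],
                                        sim$copy_truth))
  stoich <- list(fixed = est$fixed,
                 isoIII_variants = est$isoIII_variants,
                 balanced = balanced_representation(est))

  list(seed = seed, architecture = architecture, repeat_scan = repeat_scan,
       activity = activity, read_support = read_support, depth = depth,
       stoichiometry = stoich)
}

## Coordinates of the two copies of a repeat segment within an isoform
## sequence, as a repeat-pair row (0-based half-open).
planted_pair <- function(genome, iso_name, seg_id) {
  lay <- genome$layouts[[iso_name]]
  hits <- which(lay$segment == seg_id)
  if (length(hits) < 2L)
    stop("segment ", seg_id, " does not occur twice in ", iso_name)
  data.frame(copy1_start = lay$start[hits[1L]], copy1_end = lay$end[hits[1L]],
             copy2_start = lay$start[hits[2L]], copy2_end = lay$end[hits[2L]])
}

#' One-line textual summary of a pipeline report
#' @param report result of [run_synthetic_pipeline()].
#' @return character vector of summary lines (also printed).
#' @export
summarize_pipeline <- function(report) {
  a <- report$architecture
  lines <- c(
    sprintf("segments: %d | junctions: %d | isoforms: %d (%d masters + %d subgenomes)",
            a$n_segments, a$n_junctions, a$n_isoforms, a$n_masters,
            a$n_subgenomes),
    sprintf("iso1 length: %d bp | edges: %s (sum %d bp)", a$iso1_length,
            paste(a$edge_lengths, collapse = " + "), sum(a$edge_lengths)),
    sprintf("direct repeat pairs recovered: %d", report$repeat_scan$n_direct),
    sprintf("activity Rep1: %.3f (%s) | Rep2: %.3f (%s)",
            report$activity$Rep1$activity, report$activity$Rep1$classification,
            report$activity$Rep2$activity, report$activity$Rep2$classification),
    sprintf("junctions supported by reads: %d / %d",
            sum(report$read_support$junction_support$support > 0),
            nrow(report$read_support$junction_support)),
    sprintf("copy-number recovery r = %.4f", report$depth$recovery_r),
    sprintf("fixed stoichiometry: %s",
            paste(signif(report$stoichiometry$fixed, 3), collapse = " : ")),
    sprintf("balanced stoichiometry: %s",
            paste(signif(report$stoichiometry$balanced, 3), collapse = " : ")))
  cat(lines, sep = "\n")
  invisible(lines)
}
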