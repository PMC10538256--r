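## Per-repeat recombination activity from long reads: a four-reference
## construction per repeat pair (parental flank compositions M1/M2, and the
## two recombined compositions R1/R2), read assignment under identity and
## flank-coverage thresholds, and classification of the resulting activity.

circ_substr <- function(seq, start0, len) {
  n <- nchar(seq)
  start0 <- ((start0 %% n) + n) %% n
  if (start0 + len <= n) return(substr(seq, start0 + 1L, start0 + len))
  paste0(substr(seq, start0 + 1L, n), circ_substr(seq, 0L, len - (n - start0)))
}

#' Build the four flank-composition references for a repeat pair
#'
#' For a repeat with copies 1 and 2, recombination between the copies swaps
#' their downstream flanks. The four references are each `left flank +
#' repeat unit + right flank`: `M1`/`M2` carry the parental flank
#' compositions of copy 1 and copy 2 as found in the assembly, while
#' `R1`/`R2` carry the two recombined compositions (copy 1's left flank
#' with copy 2's right flank, and vice versa).
#'
#' @param genome reference sequence (character); treated as circular when
#'   `circular = TRUE`, otherwise flanks running off an end are an error.
#' @param pair one row of a [find_repeat_pairs()] data.frame (or any list
#'   with `copy1_start`, `copy1_end`, `copy2_start`, `copy2_end`).
#' @param flank flank length in bp (> 0).
#' @param circular extract flanks across the origin.
#' @return object of class `flank_set`: list with `references` (named
#'   character vector M1, M2, R1, R2), `unit_length`, `flank`, `pair`.
#' @export
build_flank_references <- function(genome, pair, flank = 1000L,
                                   circular = TRUE) {
  if (flank <= 0L)
    stop("flank must be positive: with no flanks the four references are ",
         "identical and recombination states cannot be distinguished")
  genome <- as.character(genome)
  n <- nchar(genome)
  unit_len <- pair$copy1_end - pair$copy1_start
  if (!circular) {
    lo <- min(pair$copy1_start, pair$copy2_start) - flank
    hi <- max(pair$copy1_end, pair$copy2_end) + flank
    if (lo < 0L || hi > n)
      stop("flank extends beyond the linear reference; use circular = TRUE")
  }
  unit <- circ_substr(genome, pair$copy1_start, unit_len)
  L1 <- circ_substr(genome, pair$copy1_start - flank, flank)
  R1f <- circ_substr(genome, pair$copy1_end, flank)
  L2 <- circ_substr(genome, pair$copy2_start - flank, flank)
  R2f <- circ_substr(genome, pair$copy2_end, flank)
  refs <- c(M1 = paste0(L1, unit, R1f),
            M2 = paste0(L2, unit, R2f),
            R1 = paste0(L1, unit, R2f),
            R2 = paste0(L2, unit, R1f))
  if (identical(L1, L2) || identical(R1f, R2f))
    warning("parental and recombined flank compositions are identical; ",
            "M and R references are indistinguishable for this pair")
  structure(list(references = refs, unit_length = unit_len, flank = flank,
                 pair = pair),
            class = "flank_set")
}

#' Assign long reads to flank-composition references
#'
#' A read is assigned to the unique reference on which its best local
#' alignment reaches `min_identity` and covers at least `min_flank_cov` of
#' both flank windows. Reads qualifying on more than one reference are
#' discarded as ambiguous and tallied; reads qualifying nowhere are
#' unassigned.
#'
#' @param reads named character vector of read sequences.
#' @param flank_set a [build_flank_references()] object.
#' @param min_identity minimum alignment identity.
#' @param min_flank_cov minimum covered fraction of each flank window.
#' @param k anchor k-mer length.
#' @return list with `counts` (named integer M1, M2, R1, R2),
#'   `n_ambiguous`, `n_unassigned`, `assignments` (per-read data.frame).
#' @export
assign_reads <- function(reads, flank_set, min_identity = 0.80,
                         min_flank_cov = 0.80, k = 13L) {
  refs <- flank_set$references
  flank <- flank_set$flank
  unit_len <- flank_set$unit_length
  ref_len <- flank + unit_len + flank
  refs_i <- lapply(refs, seq_index, k = k)
  counts <- setNames(integer(4L), names(refs))
  n_amb <- 0L; n_un <- 0L
  rows <- list()
  for (ri in seq_along(reads)) {
    qual <- character(0)
    for (nm in names(refs)) {
      mm <- match_read(reads[[ri]], refs_i[[nm]], min_id = min_identity)
      if (is.null(mm)) next
      if (mm$identity < min_identity) next
      covL <- max(0L, min(mm$ref_end, flank) - max(mm$ref_start - 1L, 0L)) / flank
      covR <- max(0L, min(mm$ref_end, ref_len) -
                    max(mm$ref_start - 1L, flank + unit_len)) / flank
      if (covL >= min_flank_cov && covR >= min_flank_cov)
        qual <- c(qual, nm)
    }
    status <- if (length(qual) == 1L) qual
    else if (length(qual) > 1L) "ambiguous" else "unassigned"
    if (length(qual) == 1L) counts[qual] <- counts[qual] + 1L
    else if (length(qual) > 1L) n_amb <- n_amb + 1L
    else n_un <- n_un + 1L
    rows[[ri]] <- data.frame(
      read = if (!is.null(names(reads))) names(reads)[ri] else
        as.character(ri),
      assigned = status, stringsAsFactors = FALSE)
  }
  list(counts = counts, n_ambiguous = n_amb, n_unassigned = n_un,
       assignments = do.call(rbind, rows))
}

#' Recombination activity from reference counts
#'
#' Activity is the fraction of assigned reads carrying a recombined flank
#' composition: `(R1 + R2) / (M1 + M2 + R1 + R2)`.
#'
#' @param counts named integer vector with entries M1, M2, R1, R2.
#' @return list with `counts`, `activity` (NA when no reads assigned) and
#'   `classification` from [classify_activity()].
#' @export
activity_estimate <- function(counts) {
  tot <- sum(counts)
  act <- if (tot > 0) unname((counts["R1"] + counts["R2"]) / tot) else NA_real_
  list(counts = counts, activity = act,
       classification = if (is.na(act)) "no_data" else classify_activity(act))
}

#' Classify a recombination activity value
#'
#' Repeats with activity near one half recombine freely
#' (recombinationally active); a small but nonzero recombined fraction
#' indicates substoichiometric forms; exactly zero is inactive. Values
#' between the two thresholds are labeled indeterminate rather than forced
#' into a class.
#'
#' @param activity fraction in \[0, 1\].
#' @param active_threshold at or above: `"active"`.
#' @param substoich_threshold strictly below (and > 0):
#'   `"substoichiometric"`.
#' @return character classification.
#' @export
classify_activity <- function(activity, active_threshold = 0.05,
                              substoich_threshold = 0.02) {
  stopifnot(activity >= 0, activity <= 1)
  if (activity >= active_threshold) "active"
  else if (activity == 0) "inactive"
  else if (activity < substoich_threshold) "substoichiometric"
  else "indeterminate"
}
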