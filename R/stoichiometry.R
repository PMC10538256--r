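## From segment copy numbers to subgenome stoichiometry. Because short-read
## depth cannot see which reversible recombination reactions are "open",
## copy numbers are first expressed in a fixed representation in which the
## smallest subgenome of the interconvertible pair group is set to zero
## (isoIV' = 0); the redundant algebra then gives three independent
## formulations of isoIII', whose disagreement diagnoses molecules outside
## the main isoform pool.

#' Fixed-representation subgenome stoichiometry from segment copy numbers
#'
#' Under the nine-segment architecture, the copy numbers of segments `e`,
#' `i` and `g` equal the copy numbers of isoI', isoII' and isoV'
#' respectively, isoIV' is zero by construction, and isoIII' is measurable
#' three independent ways: `h - g`, `c - e`, and `a - f`. All three are
#' reported; their spread is a diagnostic for isoform compositions outside
#' the five-subgenome model. Negative values arising from depth noise are
#' reported as-is and flagged, not clipped, so cohort statistics stay
#' unbiased.
#'
#' @param copy_numbers named numeric vector with segments
#'   `a,b,c,d,e,f,g,h,i` (from [segment_copy_number()]).
#' @return object of class `stoich_estimate`: list with `fixed` (isoI',
#'   isoII', isoIII' (the `hg` variant), isoIV', isoV'), `isoIII_variants`
#'   (hg, ce, af), `spread` (max - min of the variants), `negative_flag`.
#' @export
fixed_representation <- function(copy_numbers) {
  need <- c("a", "c", "e", "f", "g", "h", "i")
  miss <- setdiff(need, names(copy_numbers))
  if (length(miss))
    stop("missing segment copy number(s): ", paste(miss, collapse = ", "))
  cn <- copy_numbers
  variants <- c(hg = unname(cn["h"] - cn["g"]),
                ce = unname(cn["c"] - cn["e"]),
                af = unname(cn["a"] - cn["f"]))
  fixed <- c(isoI = unname(cn["e"]), isoII = unname(cn["i"]),
             isoIII = unname(variants["hg"]), isoIV = 0,
             isoV = unname(cn["g"]))
  structure(list(fixed = fixed,
                 isoIII_variants = variants,
                 spread = max(variants) - min(variants),
                 negative_flag = any(c(fixed, variants) < 0)),
            class = "stoich_estimate")
}

#' @export
print.stoich_estimate <- function(x, ...) {
  cat("fixed representation (isoI':isoII':isoIII':isoIV':isoV') =",
      paste(signif(x$fixed, 4), collapse = " : "), "\n")
  cat("isoIII' variants hg/ce/af:",
      paste(signif(x$isoIII_variants, 4), collapse = " / "),
      "| spread", signif(x$spread, 3), "\n")
  if (x$negative_flag) cat("note: negative value(s) present (noise)\n")
  invisible(x)
}

#' Balanced representation under the equal-pairs assumption
#'
#' The pair isoI + isoV interconverts with isoIII + isoIV, so the fixed
#' representation (which forces isoIV' = 0) understates isoIII/isoIV.
#' Assuming equal numbers of the two pair states, half of
#' `min(isoI', isoV')` is transferred from each of isoI' and isoV' into
#' isoIII and isoIV.
#'
#' @param est a [fixed_representation()] object (or a numeric vector of
#'   five fixed copy numbers).
#' @return named numeric vector isoI..isoV.
#' @export
balanced_representation <- function(est) {
  f <- if (inherits(est, "stoich_estimate")) est$fixed else
    setNames(as.numeric(est), c("isoI", "isoII", "isoIII", "isoIV", "isoV"))
  t <- min(f["isoI"], f["isoV"]) / 2
  out <- c(isoI = unname(f["isoI"] - t), isoII = unname(f["isoII"]),
           isoIII = unname(f["isoIII"] + t), isoIV = unname(f["isoIV"] + t),
           isoV = unname(f["isoV"] - t))
  out
}

#' Consistency of the three isoIII' formulations across a cohort
#'
#' Summarizes each formulation's distribution over samples, reports the
#' pairwise median differences, and flags formulation pairs whose observed
#' ranges do not overlap — the signature of systematic extra molecules
#' (e.g. overlapping linear forms) rather than noise. A rank-sum p-value
#' is reported alongside but the flag is the range criterion.
#'
#' @param estimates list of [fixed_representation()] objects (>= 1).
#' @return list with `summary` (per-formulation median/IQR/min/max),
#'   `pairwise` (data.frame of median differences, overlap flags and
#'   rank-sum p-values; NULL for a single sample).
#' @export
formulation_consistency <- function(estimates) {
  v <- t(vapply(estimates, function(e) e$isoIII_variants, numeric(3)))
  colnames(v) <- c("hg", "ce", "af")
  summ <- data.frame(
    formulation = colnames(v),
    median = apply(v, 2, median),
    iqr = apply(v, 2, IQR),
    min = apply(v, 2, min),
    max = apply(v, 2, max),
    row.names = NULL, stringsAsFactors = FALSE)
  if (nrow(v) < 2L)
    return(list(summary = summ, pairwise = NULL))
  combs <- utils::combn(colnames(v), 2)
  pw <- lapply(seq_len(ncol(combs)), function(k) {
    x <- v[, combs[1L, k]]; y <- v[, combs[2L, k]]
    overlap <- min(max(x), max(y)) >= max(min(x), min(y))
    pval <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(pair = paste(combs[1L, k], combs[2L, k], sep = "-"),
               median_diff = median(y) - median(x),
               ranges_overlap = overlap,
               nonoverlap_flag = !overlap,
               p_ranksum = pval, stringsAsFactors = FALSE)
  })
  list(summary = summ, pairwise = do.call(rbind, pw))
}

#' Per-group segment copy-number summaries and overlap report
#'
#' For grouped samples (populations, tissues), summarizes the distribution
#' of relative copy number per segment and reports, for every segment and
#' pair of groups, whether the per-group observed ranges intersect.
#' Relative copy number is each sample's copy vector divided by its mean
#' over segments, removing per-sample mitochondrial abundance.
#'
#' @param copy_tables named list of groups; each group is a list of named
#'   copy-number vectors (one per sample). Empty groups are dropped with a
#'   warning.
#' @return list with `table` (long data.frame: group, segment, median,
#'   min, max, n) and `overlap` (data.frame: segment, group1, group2,
#'   ranges_overlap).
#' @export
cohort_summary <- function(copy_tables) {
  sizes <- vapply(copy_tables, length, 0L)
  if (any(sizes == 0L)) {
    warning("dropping empty group(s): ",
            paste(names(copy_tables)[sizes == 0L], collapse = ", "))
    copy_tables <- copy_tables[sizes > 0L]
  }
  rel <- lapply(copy_tables, function(grp)
    do.call(rbind, lapply(grp, function(cn) cn / mean(cn))))
  tab <- do.call(rbind, lapply(names(rel), function(g) {
    m <- rel[[g]]
    data.frame(group = g, segment = colnames(m),
               median = apply(m, 2, median),
               min = apply(m, 2, min), max = apply(m, 2, max),
               n = nrow(m), row.names = NULL, stringsAsFactors = FALSE)
  }))
  groups <- names(rel)
  ov <- NULL
  if (length(groups) >= 2L) {
    combs <- utils::combn(groups, 2)
    for (k in seq_len(ncol(combs))) {
      g1 <- combs[1L, k]; g2 <- combs[2L, k]
      t1 <- tab[tab$group == g1, ]; t2 <- tab[tab$group == g2, ]
      segs <- intersect(t1$segment, t2$segment)
      for (s in segs) {
        r1 <- t1[t1$segment == s, ]; r2 <- t2[t2$segment == s, ]
        ov <- rbind(ov, data.frame(
          segment = s, group1 = g1, group2 = g2,
          ranges_overlap = min(r1$max, r2$max) >= max(r1$min, r2$min),
          stringsAsFactors = FALSE))
      }
    }
  }
  list(table = tab, overlap = ov)
}
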