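#' @importFrom stats median rnorm rpois runif quantile wilcox.test IQR setNames
#' @importFrom utils read.table write.table head tail
#' @import data.table
NULL

.datatable.aware <- TRUE

#' Lower-median of a numeric vector
#'
#' Deterministic median convention used for depth statistics: for an even
#' number of values the lower of the two middle order statistics is
#' returned, so the result is always an observed value.
#'
#' @param x numeric vector (NAs removed).
#' @return a single numeric value, or `NA` if `x` is empty.
#' @export
median_low <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[ceiling(n / 2)]
}

## Run code under a private RNG state so generators are reproducible under a
## seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Random DNA of length n (uniform alphabet).
random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Reverse complement of a plain character string.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Encode a DNA string as integers 0..3 (anything else -> NA).
dna_to_int <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[v])
}

## Rolling k-mer codes (base-4) of an integer-encoded sequence; k <= 26 so
## codes stay exact in doubles. Positions with ambiguous bases yield NA.
kmer_codes <- function(xi, k) {
  n <- length(xi)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) code <- code + xi[(1L + j):(m + j)] * 4^(k - 1L - j)
  code
}

## Merge a set of 0-based half-open intervals given as a 2-col matrix.
merge_intervals <- function(mat) {
  if (is.null(mat) || nrow(mat) == 0L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  ir <- IRanges::reduce(IRanges::IRanges(start = mat[, 1] + 1L, end = mat[, 2]))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
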