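## Shared toy construction: a repeat unit with four distinct flanks, giving
## a genome in which the M/R flank compositions are fully distinguishable.
make_flank_toy <- function(unit_len = 2000L, flank = 1000L, seed = 21) {
  set.seed(seed)
  unit <- rnd_dna(unit_len)
  fl <- replicate(4, rnd_dna(flank))  # L1, R1, L2, R2
  genome <- paste0(rnd_dna(500), fl[1], unit, fl[2], rnd_dna(4000),
                   fl[3], unit, fl[4], rnd_dna(500))
  pair <- data.frame(copy1_start = 500L + flank,
                     copy1_end = 500L + flank + unit_len,
                     copy2_start = 500L + flank + unit_len + flank + 4000L + flank,
                     copy2_end = 500L + flank + unit_len + flank + 4000L +
                       flank + unit_len)
  list(genome = genome, pair = pair, unit = unit, flanks = fl)
}

test_that("flank references have the M/R composition structure", {
  toy <- make_flank_toy()
  fs <- build_flank_references(toy$genome, toy$pair, flank = 1000L)
  expect_named(fs$references, c("M1", "M2", "R1", "R2"))
  expect_true(all(nchar(fs$references) == 2000 + 2000))
  ## all four share the repeat-unit core
  cores <- substr(fs$references, 1001, 1000 + 2000)
  expect_true(all(cores == toy$unit))
  ## M1 = L1 + unit + R1; R1 = L1 + unit + R2
  expect_equal(substr(fs$references[["M1"]], 1, 1000), toy$flanks[1])
  expect_equal(substr(fs$references[["R1"]], 3001, 4000), toy$flanks[4])
})

test_that("fixture repeat flank references have the documented length", {
  fx <- zm9_fixture()
  genome <- synth_genome(fx, seed = 3)
  pr <- mitoforms:::planted_pair(genome, "iso1", "d")
  fs <- build_flank_references(genome$isoform_seqs[["iso1"]], pr)
  expect_true(all(nchar(fs$references) == 4845 + 2000))
})

test_that("degenerate flank configurations are rejected or flagged", {
  toy <- make_flank_toy()
  expect_error(build_flank_references(toy$genome, toy$pair, flank = 0L),
               "flank")
  ## flanks running off a linear reference
  small_pair <- data.frame(copy1_start = 100L, copy1_end = 300L,
                           copy2_start = 3000L, copy2_end = 3200L)
  expect_error(build_flank_references(substr(toy$genome, 1, 4000),
                                      small_pair, flank = 1000L,
                                      circular = FALSE), "circular")
  ## identical flank compositions are indistinguishable
  set.seed(22)
  unit <- rnd_dna(1000)
  shared <- rnd_dna(1000)
  genome <- paste0(shared, unit, shared, rnd_dna(3000), shared, unit, shared)
  pair <- data.frame(copy1_start = 1000L, copy1_end = 2000L,
                     copy2_start = 7000L, copy2_end = 8000L)
  expect_warning(build_flank_references(genome, pair, flank = 1000L),
                 "indistinguishable")
})

test_that("error-free reads are assigned to their reference of origin", {
  toy <- make_flank_toy()
  fs <- build_flank_references(toy$genome, toy$pair, flank = 1000L)
  asn <- assign_reads(fs$references["M1"], fs)  # the M1 sequence as a read
  expect_equal(unname(asn$counts["M1"]), 1L)
  expect_equal(sum(asn$counts), 1L)
})

test_that("a read covering one flank below threshold is unassigned", {
  toy <- make_flank_toy()
  fs <- build_flank_references(toy$genome, toy$pair, flank = 1000L)
  ## 790 of 1000 bp of the left flank (79% < 80%), full unit + right flank
  read79 <- substr(fs$references[["M1"]], 211, 4000)
  asn <- assign_reads(c(r1 = read79), fs)
  expect_equal(sum(asn$counts), 0L)
  expect_equal(asn$n_unassigned, 1L)
  ## at 80% coverage the same read qualifies
  read80 <- substr(fs$references[["M1"]], 201, 4000)
  asn2 <- assign_reads(c(r1 = read80), fs)
  expect_equal(unname(asn2$counts["M1"]), 1L)
})

test_that("activity estimates recover the true recombined fraction", {
  toy <- make_flank_toy()
  fs <- build_flank_references(toy$genome, toy$pair, flank = 1000L)
  n <- 200L
  for (p in c(0, 0.1, 0.5)) {
    w <- c(M1 = (1 - p) / 2, M2 = (1 - p) / 2, R1 = p / 2, R2 = p / 2)
    rds <- simulate_long_reads(fs$references, weights = w, n = n,
                               length_mean = 4000, length_sd = 0,
                               error_rate = 0, seed = 100 + round(p * 10),
                               circular = FALSE)
    est <- activity_estimate(assign_reads(rds$reads, fs)$counts)
    ## 95% binomial interval around p at n = 200
    lo <- qbinom(0.025, n, p) / n
    hi <- qbinom(0.975, n, p) / n
    expect_gte(est$activity, lo)
    expect_lte(est$activity, hi)
  }
})

test_that("swapping M and R labels inverts the activity", {
  toy <- make_flank_toy()
  fs <- build_flank_references(toy$genome, toy$pair, flank = 1000L)
  w <- c(M1 = 0.35, M2 = 0.35, R1 = 0.15, R2 = 0.15)
  rds <- simulate_long_reads(fs$references, weights = w, n = 120L,
                             length_mean = 4000, length_sd = 0,
                             error_rate = 0, seed = 33, circular = FALSE)
  counts <- assign_reads(rds$reads, fs)$counts
  act <- activity_estimate(counts)$activity
  swapped <- counts[c("R1", "R2", "M1", "M2")]
  names(swapped) <- c("M1", "M2", "R1", "R2")
  expect_equal(activity_estimate(swapped)$activity, 1 - act)
})

test_that("noisy reads still classify correctly on assignable reads", {
  toy <- make_flank_toy()
  fs <- build_flank_references(toy$genome, toy$pair, flank = 1000L)
  w <- c(M1 = 0.5, M2 = 0.5, R1 = 0, R2 = 0)
  rds <- simulate_long_reads(fs$references[c("M1", "M2")], n = 60L,
                             length_mean = 4000, length_sd = 0,
                             error_rate = 0.1, seed = 44, circular = FALSE)
  asn <- assign_reads(rds$reads, fs)
  assigned <- sum(asn$counts)
  expect_gt(assigned, 0L)
  ## no read of parental origin may land on a recombined reference
  correct <- asn$counts[["M1"]] + asn$counts[["M2"]]
  expect_gte(correct / assigned, 0.95)
})

test_that("activity classification uses the documented bands", {
  expect_equal(classify_activity(0.531), "active")
  expect_equal(classify_activity(0.05), "active")
  expect_equal(classify_activity(0), "inactive")
  expect_equal(classify_activity(0.01), "substoichiometric")
  expect_equal(classify_activity(0.03), "indeterminate")
  expect_error(classify_activity(1.2))
  expect_equal(activity_estimate(c(M1 = 0L, M2 = 0L, R1 = 0L, R2 = 0L))$classification,
               "no_data")
})
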