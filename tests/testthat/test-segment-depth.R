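test_that("lower-median convention is deterministic", {
  expect_equal(median_low(c(1, 2, 3)), 2)
  expect_equal(median_low(c(1, 2, 3, 10)), 2)  # lower middle of even count
  expect_equal(median_low(c(4, 1)), 1)
  expect_true(is.na(median_low(numeric(0))))
})

test_that("max-merging two linearizations removes break-point artifacts", {
  n <- 1000L
  ## uniform depth stays uniform
  pr <- circular_depth(rep(50L, n), rep(50L, n), rotation_offset = 500L)
  expect_true(all(pr$depth == 50))
  ## depth dipping to zero only at each linearization's break point
  d1 <- rep(50L, n); d1[c(1:25, (n - 24):n)] <- 0L
  d2 <- rep(50L, n); d2[c(1:25, (n - 24):n)] <- 0L
  merged <- circular_depth(d1, d2, rotation_offset = 500L)
  expect_true(all(merged$depth > 0))
  ## identical break points are rejected
  expect_error(circular_depth(d1, d2, rotation_offset = 0L), "break points")
  ## empty alignments give an all-zero profile
  z <- circular_depth(rep(0L, n), rep(0L, n), 500L)
  expect_true(all(z$depth == 0))
})

test_that("planted NUMTs are masked and overlapping insertions merge", {
  set.seed(51)
  mito <- rnd_dna(20000)
  bg <- rnd_dna(30000)
  planted <- plant_numt(bg, mito, data.frame(start = 5000L, end = 7000L),
                        seed = 52)
  mask <- mask_homology(mito, planted$nuclear)
  expect_equal(nrow(mask), 1L)
  ## the mask covers the planted interval (within extension slack)
  expect_lte(mask$start, 5000L)
  expect_gte(mask$end, 7000L)
  expect_lt(mask$end - mask$start, 2200L)
  ## unrelated background: no mask
  expect_equal(nrow(mask_homology(mito, rnd_dna(30000))), 0L)
  ## two overlapping fragments merge into one truth interval
  two <- plant_numt(bg, mito, data.frame(start = c(5000L, 6500L),
                                         end = c(7000L, 8000L)), seed = 53)
  expect_equal(nrow(two$mask_truth), 1L)
  expect_equal(two$mask_truth$start, 5000L)
  expect_equal(two$mask_truth$end, 8000L)
  ## precomputed masks are merged and passed through
  pre <- mask_homology(mito, precomputed = data.frame(start = c(10L, 50L),
                                                      end = c(60L, 90L)))
  expect_equal(pre, data.frame(start = 10L, end = 90L))
})

test_that("target coverage is the halved mean of single-copy gene depths", {
  expect_equal(target_coverage(rep(50, 67)), 25)
  expect_equal(target_coverage(c(40, 60)), 25)
  expect_error(target_coverage(numeric(0)), "gene depths")
  ## diploid Poisson simulation recovers the haplotype depth within 5%
  set.seed(54)
  gd <- vapply(1:67, function(i) mean(rpois(3000, 2 * 25)), 0)
  expect_lt(abs(target_coverage(gd) - 25) / 25, 0.05)
})

test_that("segment copy number is masked median over target", {
  bed <- data.frame(segment = c("s1", "s2"), start = c(0L, 1000L),
                    end = c(1000L, 3000L))
  pr <- depth_profile(c(rep(100L, 1000L), rep(50L, 2000L)))
  cn <- segment_copy_number(pr, bed, target = 50)
  expect_equal(cn$copy_number, c(2, 1))
  ## doubling depth over a masked half leaves the median untouched
  d <- c(rep(100L, 500L), rep(200L, 500L), rep(50L, 2000L))
  cn2 <- segment_copy_number(depth_profile(d), bed,
                             mask = data.frame(start = 500L, end = 1000L),
                             target = 50)
  expect_equal(cn2$copy_number[1], 2)
  ## a fully masked segment is flagged, not silently dropped
  cn3 <- segment_copy_number(pr, bed,
                             mask = data.frame(start = 0L, end = 1000L),
                             target = 50)
  expect_false(cn3$qc_pass[1])
  expect_true(is.na(cn3$copy_number[1]))
  expect_error(segment_copy_number(pr, bed, target = 0), "target")
})

test_that("copy numbers are scale-invariant in depth and target", {
  bed <- data.frame(segment = "s", start = 0L, end = 500L)
  set.seed(55)
  d <- rpois(500, 80)
  cn1 <- segment_copy_number(depth_profile(d), bed, target = 40)
  cn2 <- segment_copy_number(depth_profile(3L * d), bed, target = 120)
  expect_equal(cn1$copy_number, cn2$copy_number)
})

test_that("simulated equal-stoichiometry depth recovers the membership copy vector", {
  fx <- zm9_fixture()
  genome <- synth_genome(fx, seed = 60)
  sigma <- setNames(rep(1, 5), fx$subgenomes)
  sim <- simulate_depth(sigma, genome, target = 50, seed = 61)
  tc <- target_coverage(sim$gene_depths)
  cn <- segment_copy_number(sim$profile, genome$segments_bed, target = tc)
  truth <- c(3, 5, 2, 4, 2, 3, 2, 2, 1)
  expect_gt(cor(cn$copy_number, truth), 0.99)
  expect_true(all(abs(cn$copy_number - truth) < 0.25))
})

test_that("QC filtering applies the depth threshold inclusively and honors cohort flags", {
  samples <- data.frame(sample = c("s1", "s2", "s3", "s4"),
                        b_depth = c(39, 40, 120, 80),
                        excluded = c(FALSE, FALSE, FALSE, TRUE))
  out <- qc_filter(samples, min_depth = 40)
  expect_equal(out$kept$sample, c("s2", "s3"))
  expect_equal(nrow(out$log), 2L)
  expect_match(out$log$reason[out$log$sample == "s1"], "depth")
  expect_match(out$log$reason[out$log$sample == "s4"], "cohort")
})

test_that("duplication scan flags a planted segmental duplication and nothing else", {
  fx <- zm9_fixture()
  genome <- synth_genome(fx, seed = 62)
  bed <- genome$segments_bed
  sigma <- setNames(rep(1, 5), fx$subgenomes)
  ## duplication covering all of segment a and the first 40% of h
  a_iv <- bed[bed$segment == "a", ]
  h_iv <- bed[bed$segment == "h", ]
  h_cut <- h_iv$start + round(0.4 * (h_iv$end - h_iv$start))
  sim <- simulate_depth(sigma, genome, target = 50, seed = 63,
                        dup_region = c(a_iv$start, a_iv$end), dup_fold = 2)
  sim2 <- simulate_depth(sigma, genome, target = 50, seed = 63,
                         dup_region = c(h_iv$start, h_cut), dup_fold = 2)
  ## a duplication of the whole of segment a needs an external expected
  ## baseline (its own median doubles with it)
  an_a <- duplication_scan(sim$profile, bed,
                           baseline = 50 * sim$copy_truth)
  expect_true("a" %in% an_a$segment)
  expect_gt(sum(an_a$end[an_a$segment == "a"] -
                  an_a$start[an_a$segment == "a"]),
            0.9 * (a_iv$end - a_iv$start))
  an_h <- duplication_scan(sim2$profile, bed)
  expect_true("h" %in% an_h$segment)
  expect_lt(max(an_h$end[an_h$segment == "h"]), h_cut + 2000L)
  ## clean simulation: no anomaly anywhere
  clean <- simulate_depth(sigma, genome, target = 50, seed = 64)
  expect_equal(nrow(duplication_scan(clean$profile, bed)), 0L)
  ## a sub-threshold spike stays below the fold cutoff
  d <- rep(100L, 5000L); d[1:1000] <- 140L
  spike_bed <- data.frame(segment = "s", start = 0L, end = 5000L)
  expect_equal(nrow(duplication_scan(depth_profile(d), spike_bed)), 0L)
})
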