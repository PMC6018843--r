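test_that("variant filter applies coverage, read-count and frequency thresholds", {
  counts <- data.frame(
    marker = paste0("m", 1:6), chrom = "D12",
    pos = (1:6) * 1000,
    donor_reads = c(5, 3, 8, 2, 4, 7),
    total_reads = c(9, 10, 20, 10, 10, 20))
  filt <- filter_pooled_variants(counts)
  # survives iff coverage >= 10 AND donor reads >= 3 AND frequency >= 0.35
  expect_equal(filt$marker, c("m3", "m5", "m6"))
  rep <- attr(filt, "filter_report")
  expect_equal(unname(rep["input"]), 6L)
  expect_equal(unname(rep["removed_coverage"]), 1L)
  expect_equal(unname(rep["removed_variant_reads"]), 1L)
  expect_equal(unname(rep["removed_frequency"]), 1L)
  expect_equal(unname(rep["retained"]), 3L)
})

test_that("variant filter drops flagged indels unless asked otherwise", {
  counts <- data.frame(chrom = "A01", pos = c(100, 200),
                       donor_reads = c(10, 10), total_reads = c(20, 20),
                       is_indel = c(TRUE, FALSE))
  expect_equal(nrow(filter_pooled_variants(counts)), 1)
  expect_equal(nrow(filter_pooled_variants(counts, snps_only = FALSE)), 2)
})

test_that("pool frequency from genotype codes excludes missing values", {
  expect_equal(pool_frequency_from_genotypes(c(1, 1, 1)), 1.0)
  expect_equal(pool_frequency_from_genotypes(c(1, 0.5, 0, 0.5)), 0.5)
  expect_equal(pool_frequency_from_genotypes(c(1, NA, 0)), 0.5)
  expect_warning(f <- pool_frequency_from_genotypes(c(NA, NA)), "missing")
  expect_true(is.na(f))
  expect_error(pool_frequency_from_genotypes(c(0.3)), "codes")
})

test_that("pool frequency from reads handles zero coverage", {
  expect_equal(pool_frequency_from_reads(10, 20), 0.5)
  expect_equal(pool_frequency_from_reads(20, 20), 1.0)
  expect_equal(pool_frequency_from_reads(0, 15), 0.0)
  expect_warning(f <- pool_frequency_from_reads(0, 0), "coverage")
  expect_true(is.na(f))
  expect_error(pool_frequency_from_reads(5, 4), "donor_reads")
})

test_that("window scan matches spec'd membership on small examples", {
  # constant input: every defined window carries that value
  tr <- sliding_window_frequency(seq(1e5, 1.9e6, by = 1e5),
                                 rep(0.7, 19), 2e6)
  expect_equal(tr$freq[tr$n_snps > 0],
               rep(0.7, sum(tr$n_snps > 0)))
  # single marker at 1.2 Mb on a 2 Mb chromosome: defined only in the
  # windows starting at 500 kb and 1 Mb
  tr1 <- sliding_window_frequency(1200000, 0.8, 2e6)
  expect_equal(tr1$start[!is.na(tr1$freq)], c(5e5, 1e6))
  # no markers: all windows undefined with zero snps
  tr0 <- sliding_window_frequency(numeric(0), numeric(0), 2e6)
  expect_true(all(is.na(tr0$freq)))
  expect_true(all(tr0$n_snps == 0))
  expect_error(sliding_window_frequency(3e6, 0.5, 2e6), "beyond")
})

test_that("window track geometry follows the configured grid", {
  tr <- sliding_window_frequency(1, 0.5, 2.2e6)
  expect_equal(diff(tr$start), rep(5e5, nrow(tr) - 1))
  # trailing partial window is emitted and truncated at the chromosome end
  expect_equal(tr$end[nrow(tr)], 2.2e6)
  expect_true(all(tr$end - tr$start <= 1e6))
})

test_that("windowed means agree with a brute-force oracle on random chromosomes", {
  set.seed(20240917)
  for (i in 1:200) {
    len <- sample(2e6:8e6, 1)
    nm <- sample(0:40, 1)
    pos <- if (nm > 0) sample(len, nm) else numeric(0)
    freq <- runif(nm)
    step <- sample(c(2.5e5, 5e5, 1e6), 1)
    win <- step * sample(1:3, 1)
    cfg <- window_config(win, step)
    tr <- sliding_window_frequency(pos, freq, len, cfg)
    oracle <- brute_force_windows(pos, freq, len, win, step)
    expect_equal(tr$start, oracle$start)
    expect_equal(tr$n_snps, as.integer(oracle$n_snps))
    expect_equal(tr$freq, oracle$freq)
  }
})

test_that("window means stay within the range of member frequencies", {
  set.seed(7)
  pos <- sample(5e6, 60)
  freq <- runif(60)
  tr <- sliding_window_frequency(pos, freq, 5e6)
  ok <- !is.na(tr$freq)
  expect_true(all(tr$freq[ok] >= min(freq) - 1e-12))
  expect_true(all(tr$freq[ok] <= max(freq) + 1e-12))
})

test_that("genome-wide scan is invariant to marker input order", {
  set.seed(11)
  freqs <- data.frame(chrom = sample(c("A01", "A02"), 50, replace = TRUE),
                      pos = sample(4e6, 50), freq = runif(50))
  lens <- c(A01 = 4e6, A02 = 4e6)
  a <- window_scan(freqs, lens)
  b <- window_scan(freqs[sample(nrow(freqs)), ], lens)
  expect_identical(a, b)
  expect_error(window_scan(data.frame(chrom = "Z", pos = 1, freq = 0.5),
                           lens), "unknown chromosome")
})

test_that("dual-bulk region calling merges runs of qualifying windows", {
  # four consecutive qualifying windows flanked by non-qualifying ones
  rec <- toy_track(c(0.5, 0.98, 0.98, 0.98, 0.98, 0.5))
  seg <- toy_track(c(0.49, 0.49, 0.49, 0.49, 0.49, 0.49))
  reg <- call_candidate_regions(rec, seg)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 5e5)       # first qualifying window start
  expect_equal(reg$end, 4 * 5e5 + 1e6)  # last qualifying window end
  expect_equal(reg$n_windows, 4)
  expect_equal(reg$evidence, "MBS")
  expect_equal(reg$mean_freq_recessive, 0.98)
})

test_that("fixed donor background fails the segregating ~0.5 criterion", {
  rec <- toy_track(rep(0.98, 5))
  seg_fixed <- toy_track(rep(0.95, 5))   # drifted to fixation, not causal
  expect_equal(nrow(call_candidate_regions(rec, seg_fixed)), 0)
  rec_half <- toy_track(rep(0.5, 5))
  seg_half <- toy_track(rep(0.5, 5))
  expect_equal(nrow(call_candidate_regions(rec_half, seg_half)), 0)
})

test_that("undefined windows break runs and short runs are discarded", {
  rec <- toy_track(c(0.98, NA, 0.98, 0.98, 0.98))
  seg <- toy_track(rep(0.5, 5))
  reg <- call_candidate_regions(rec, seg, min_consecutive = 2)
  expect_equal(nrow(reg), 1)  # only the 3-window run after the NA
  expect_equal(reg$n_windows, 3)
  # a lone qualifying window is below min_consecutive
  rec2 <- toy_track(c(0.98, 0.5, 0.5))
  expect_equal(nrow(call_candidate_regions(rec2, toy_track(rep(0.5, 3)))), 0)
  expect_error(call_candidate_regions(rec, toy_track(rep(0.5, 4))),
               "grids")
})

test_that("raising the high threshold never enlarges or adds regions", {
  set.seed(99)
  for (i in 1:20) {
    rec <- toy_track(runif(20, 0.6, 1))
    seg <- toy_track(runif(20, 0.3, 0.7))
    lo <- call_candidate_regions(rec, seg, high_threshold = 0.8,
                                 min_consecutive = 1)
    hi <- call_candidate_regions(rec, seg, high_threshold = 0.95,
                                 min_consecutive = 1)
    if (nrow(hi) > 0) {
      contained <- vapply(seq_len(nrow(hi)), function(j) {
        any(lo$start <= hi$start[j] & lo$end >= hi$end[j])
      }, logical(1))
      expect_true(all(contained))
    }
    expect_lte(sum(hi$end - hi$start), sum(lo$end - lo$start))
  }
})

test_that("array-pool calling needs high reduced and low normal frequencies", {
  red <- toy_track(c(0.95, 0.95, 0.95))
  expect_equal(nrow(call_array_candidates(red, toy_track(rep(0.2, 3)))), 1)
  expect_equal(nrow(call_array_candidates(red, toy_track(rep(0.6, 3)))), 0)
  low_red <- toy_track(rep(0.7, 3))
  expect_equal(nrow(call_array_candidates(low_red, toy_track(rep(0.2, 3)))), 0)
})

test_that("region-set intersection keeps both-evidence and solo regions", {
  a <- data.frame(chrom = "D12", start = 10e6, end = 20e6, evidence = "MBS")
  b <- data.frame(chrom = "D12", start = 15e6, end = 30e6,
                  evidence = "array")
  out <- intersect_region_sets(a, b)
  both <- out[out$evidence == "both", ]
  expect_equal(both$start, 15e6)
  expect_equal(both$end, 20e6)
  # disjoint sets produce no both-evidence regions
  b2 <- data.frame(chrom = "A01", start = 1e6, end = 2e6,
                   evidence = "array")
  out2 <- intersect_region_sets(a, b2)
  expect_false(any(out2$evidence == "both"))
  expect_equal(nrow(out2), 2)
  # identical sets: everything both, idempotent coordinates
  out3 <- intersect_region_sets(a, transform(a, evidence = "array"))
  expect_equal(out3$evidence, "both")
  expect_equal(out3$start, a$start)
  expect_equal(out3$end, a$end)
})

test_that("array pool frequencies average codes across the pooled individuals", {
  mm <- marker_map(c("m1", "m2"), c("A01", "A01"), c(100, 200))
  gm <- genotype_matrix(mm, rbind(c(1, 1), c(0, NA), c(0.5, 1)),
                        c("i1", "i2", "i3"))
  f <- array_pool_frequencies(gm)
  expect_equal(f$freq, c(0.5, 1))  # m2 mean over i1, i3 only
  expect_equal(f$n_used, c(3L, 2L))
  f2 <- array_pool_frequencies(gm, c("i1", "i3"))
  expect_equal(f2$freq, c(0.75, 1))
  expect_error(array_pool_frequencies(gm, "nope"), "unknown individual")
})
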