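test_that("simulated genomes carry the expected marker grid", {
  g <- sim_genome()
  expect_equal(length(g$chrom_lengths), 26)
  expect_equal(nrow(g$markers), 26 * 240)
  expect_equal(unname(g$chrom_lengths[1]), 60e6)
  g2 <- tiny_genome()
  expect_equal(nrow(g2$markers), 2 * 10)
  expect_error(sim_genome(0), "positive")
})

test_that("tightly linked markers co-segregate, unlinked markers assort freely", {
  # near-zero genetic length: no recombination between markers
  g0 <- sim_genome(1, 2e6, 1e6, cm_per_mb = 1e-9)
  parent <- list(h1 = c(1, 1), h2 = c(0, 0))
  set.seed(1)
  gam <- replicate(200, simulate_gamete(parent, g0))
  expect_true(all(gam[1, ] == gam[2, ]))
  # markers on different chromosomes: recombinant fraction ~ 0.5
  g2 <- sim_genome(2, 1e6, 1e6)
  parent2 <- list(h1 = c(1, 1), h2 = c(0, 0))
  set.seed(2)
  gam2 <- replicate(10000, simulate_gamete(parent2, g2))
  rf <- mean(gam2[1, ] != gam2[2, ])
  expect_lt(abs(rf - 0.5), 0.02)
})

test_that("recombination at 20 cM matches the Haldane closed form", {
  # markers 20 Mb apart at 1 cM/Mb: d = 0.2 Morgan
  g <- sim_genome(1, 4e7, 2e7)
  parent <- list(h1 = c(1, 1), h2 = c(0, 0))
  set.seed(3)
  gam <- replicate(10000, simulate_gamete(parent, g))
  rf <- mean(gam[1, ] != gam[2, ])
  expect_lt(abs(rf - (1 - exp(-0.4)) / 2), 0.015)
})

test_that("F2 genotype classes segregate 1:2:1", {
  g <- sim_genome(1, 1e6, 5e5)
  m <- causal_model(data.frame(locus = "L", chrom = "A01", pos = 5e5,
                               role = "required_recessive", effect = 0))
  f2 <- simulate_f2(g, m, n = 10000, seed = 10)
  codes <- f2$genotypes$codes[, f2$causal_markers[["L"]]]
  obs <- c(sum(codes == 0), sum(codes == 0.5), sum(codes == 1))
  chi <- suppressWarnings(stats::chisq.test(obs, p = c(1, 2, 1) / 4))
  expect_gt(chi$p.value, 0.05)
})

test_that("fuzzless fractions match the 15:1 and 63:1 expectations", {
  g <- tiny_genome(3, 5e6, 1e6)
  loci2 <- data.frame(locus = c("a", "b"), chrom = c("A01", "A02"),
                      pos = 2e6, role = "required_recessive", effect = 0)
  f2 <- simulate_f2(g, causal_model(loci2), n = 4000, seed = 21)
  frac2 <- mean(f2$phenotypes$fuzz_class == "fuzzless")
  expect_lt(abs(frac2 - 1 / 16), 0.016)  # ~4 binomial sd
  loci3 <- rbind(loci2, data.frame(locus = "c", chrom = "A03", pos = 2e6,
                                   role = "required_recessive", effect = 0))
  f3 <- simulate_f2(g, causal_model(loci3), n = 4000, seed = 22)
  frac3 <- mean(f3$phenotypes$fuzz_class == "fuzzless")
  expect_lt(abs(frac3 - 1 / 64), 0.009)
})

test_that("the phenotype rule produces the configured means and classes", {
  m <- ps_causal_model()
  # all-required donor homozygote: residual fuzz |N(0.7, 0.4)|, so the
  # fuzzless-class probability is Phi(2) - Phi(-5.5) = 0.9772
  codes_mut <- matrix(rep(c(0, 0, 1, 1, 1), each = 2000), nrow = 2000)
  set.seed(30)
  ph <- phenotype_from_genotype(codes_mut, m)
  expect_lt(abs(mean(ph$fuzz_class == "fuzzless") - 0.97725), 0.015)
  expect_true(all(ph$fuzz_pct >= 0))
  # no donor allele anywhere: baseline-fuzz normal seeds
  codes_wt <- matrix(0, nrow = 1000, ncol = 5)
  set.seed(31)
  ph_wt <- phenotype_from_genotype(codes_wt, m)
  expect_lt(abs(mean(ph_wt$fuzz_pct) - 11), 0.25)
  expect_true(all(ph_wt$fuzz_class == "normal"))
  # one additive donor copy at locus V shifts the mean by its effect
  codes_het <- codes_wt; codes_het[, 5] <- 0.5
  set.seed(32)
  ph_het <- phenotype_from_genotype(codes_het, m)
  expect_lt(abs(mean(ph_het$fuzz_pct) - mean(ph_wt$fuzz_pct) + 2.5), 0.25)
  # enhancer homozygote raises fuzz by its effect
  codes_enh <- codes_wt; codes_enh[, 1] <- 1
  set.seed(33)
  ph_enh <- phenotype_from_genotype(codes_enh, m)
  expect_lt(abs(mean(ph_enh$fuzz_pct) - mean(ph_wt$fuzz_pct) - 3), 0.25)
  expect_error(phenotype_from_genotype(matrix(NA_real_, 1, 5), m),
               "defined")
})

test_that("recessive bulks carry only required-locus donor homozygotes", {
  g <- tiny_genome()
  m <- single_locus_model(g)
  f2 <- simulate_f2(g, m, n = 300, seed = 40)
  n_fuzzless <- sum(f2$phenotypes$fuzz_class == "fuzzless")
  set.seed(41)
  ids <- build_bulk(f2, "recessive_bulk", size = n_fuzzless)
  codes <- f2$genotypes$codes[ids, f2$causal_markers]
  expect_true(all(codes == 1))
  expect_error(build_bulk(f2, "recessive_bulk", size = n_fuzzless + 1000),
               "eligible")
})

test_that("segregating bulks average a donor frequency of one half", {
  g <- sim_genome(1, 2e6, 1e6)
  m <- causal_model(data.frame(locus = "L", chrom = "A01", pos = 1e6,
                               role = "required_recessive", effect = 0))
  means <- vapply(1:30, function(s) {
    f2 <- simulate_f2(g, m, n = 30, seed = 600 + s)
    ids <- build_bulk(f2, "segregating_bulk", size = 24)
    mean(f2$genotypes$codes[ids, f2$causal_markers])
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("pooled read counts follow the binomial sampling model", {
  nm <- 5000
  mm <- marker_map(paste0("m", seq_len(nm)), rep("A01", nm),
                   seq_len(nm) * 1e4)
  gm_fixed <- genotype_matrix(mm, matrix(1, 1, nm), "donor_ind")
  pc <- simulate_pool_counts(gm_fixed, "donor_ind", depth = 30, seed = 50)
  expect_true(all(pc$donor_reads == pc$total_reads))  # p = 1, e = 0
  gm_half <- genotype_matrix(mm, rbind(rep(1, nm), rep(0, nm)),
                             c("d", "r"))
  pc_half <- simulate_pool_counts(gm_half, c("d", "r"), depth = 30,
                                  seed = 51)
  f <- pc_half$donor_reads / pc_half$total_reads
  expect_lt(abs(mean(f, na.rm = TRUE) - 0.5), 0.01)
  pc_err <- simulate_pool_counts(gm_fixed, "donor_ind", depth = 30,
                                 error_rate = 0.01, seed = 52)
  f_err <- pc_err$donor_reads / pc_err$total_reads
  expect_lt(abs(mean(f_err, na.rm = TRUE) - 0.99), 0.005)
  expect_error(simulate_pool_counts(gm_fixed, "donor_ind", depth = 0),
               "depth")
  expect_error(simulate_pool_counts(gm_fixed, "donor_ind",
                                    error_rate = 0.6), "error_rate")
})

test_that("generators are bit-identical under a fixed seed", {
  g <- tiny_genome()
  m <- single_locus_model(g)
  a <- simulate_f2(g, m, n = 50, seed = 77)
  b <- simulate_f2(g, m, n = 50, seed = 77)
  expect_identical(a$genotypes$codes, b$genotypes$codes)
  expect_identical(a$phenotypes, b$phenotypes)
  pa <- simulate_pool_counts(a$genotypes, a$genotypes$individuals[1:10],
                             seed = 78)
  pb <- simulate_pool_counts(b$genotypes, b$genotypes$individuals[1:10],
                             seed = 78)
  expect_identical(pa, pb)
  n1 <- simulate_nil_lines(g, m, n_selfs = 2, n_fuzzless_lines = 2,
                           n_segregating_lines = 1, progeny_per_line = 4,
                           seed = 79)
  n2 <- simulate_nil_lines(g, m, n_selfs = 2, n_fuzzless_lines = 2,
                           n_segregating_lines = 1, progeny_per_line = 4,
                           seed = 79)
  expect_identical(n1$genotypes$codes, n2$genotypes$codes)
})

test_that("NIL development fixes or retains causal loci as designed", {
  g <- tiny_genome()
  m <- single_locus_model(g)
  nil <- simulate_nil_lines(g, m, n_selfs = 3, n_fuzzless_lines = 2,
                            n_segregating_lines = 2, progeny_per_line = 6,
                            seed = 80)
  causal <- nil$causal_markers
  fl <- nil$meta$individual[nil$meta$line_type == "fuzzless"]
  expect_true(all(nil$genotypes$codes[fl, causal] == 1))
  sg <- nil$meta$individual[nil$meta$line_type == "segregating"]
  # selfed progeny of heterozygous parents: mean code near 0.5
  expect_lt(abs(mean(nil$genotypes$codes[sg, causal]) - 0.5), 0.25)
  # background far from the causal locus is mostly recurrent after BC4
  bg <- setdiff(colnames(nil$genotypes$codes), causal)
  expect_lt(mean(nil$genotypes$codes[, bg]), 0.3)
})
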