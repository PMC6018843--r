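test_that("phenotypes partition by genotype code at a marker", {
  mm <- marker_map("m1", "A01", 100)
  gm <- genotype_matrix(mm, cbind(c(1, 1, 0, 0.5)),
                        c("i1", "i2", "i3", "i4"))
  pt <- phenotype_table(c("i1", "i2", "i3", "i4"), c(2, 3, 11, 7))
  g <- group_phenotype_by_genotype(gm, "m1", pt)
  expect_equal(lengths(g[c("donor", "het", "recurrent")]),
               c(donor = 2L, het = 1L, recurrent = 1L))
  expect_equal(sort(g$donor), c(2, 3))
  expect_error(group_phenotype_by_genotype(gm, "nope", pt), "marker")
})

test_that("individuals missing genotype or phenotype are excluded with notice", {
  mm <- marker_map("m1", "A01", 100)
  gm <- genotype_matrix(mm, cbind(c(1, NA, 0)), c("i1", "i2", "i3"))
  pt <- phenotype_table(c("i1", "i3"), c(2, 11))
  expect_warning(g <- group_phenotype_by_genotype(gm, "m1", pt),
                 "without phenotype")
  expect_equal(g$n_excluded, 1L)
  # individual absent from the phenotype table triggers a warning
  pt2 <- phenotype_table("i1", 2)
  expect_warning(group_phenotype_by_genotype(gm, "m1", pt2),
                 "without phenotype")
  # nothing usable at all is an error
  gm2 <- genotype_matrix(mm, cbind(c(NA_real_, NA_real_)), c("i1", "i3"))
  expect_error(suppressWarnings(
    group_phenotype_by_genotype(gm2, "m1", pt)), "no individual")
})

test_that("pooled-variance t matches the hand-computed closed form", {
  g <- make_groups(donor = c(1, 2, 3), het = numeric(0),
                   recurrent = c(4, 5, 6))
  res <- marker_trait_test(g)
  ct <- res$contrasts
  hom <- ct[ct$contrast == "donor_vs_recurrent", ]
  # frozen: sp^2 = 1, t = -3 / sqrt(2/3), p = 2 * pt(t, 4)
  expect_equal(hom$t, -3.67423461417477, tolerance = 1e-9)
  expect_equal(hom$p, 0.0213116411287567, tolerance = 1e-9)
  expect_true(hom$sig05)
  expect_false(hom$sig01)
})

test_that("identical groups give t = 0 and p = 1", {
  g <- make_groups(c(1, 2, 3), numeric(0), c(1, 2, 3))
  ct <- marker_trait_test(g)$contrasts
  expect_equal(ct$t[1], 0)
  expect_equal(ct$p[1], 1)
})

test_that("undersized groups make a contrast untestable, not an error", {
  g <- make_groups(c(1, 2), numeric(0), c(4, 5, 6))
  ct <- marker_trait_test(g, min_group_size = 3)$contrasts
  expect_true(is.na(ct$t[1]))
  expect_true(is.na(ct$p[1]))
})

test_that("the t statistic is antisymmetric and shift-invariant", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(6, 10, 2); y <- rnorm(8, 12, 2)
    a <- marker_trait_test(make_groups(x, numeric(0), y))$contrasts
    b <- marker_trait_test(make_groups(y, numeric(0), x))$contrasts
    expect_equal(a$t[1], -b$t[1])
    expect_equal(a$p[1], b$p[1])
    shifted <- marker_trait_test(make_groups(x + 7, numeric(0),
                                             y + 7))$contrasts
    expect_equal(a$t[1], shifted$t[1])
  }
})

test_that("effect classification follows mean ordering and significance", {
  set.seed(31)
  n <- 40
  # additive: het strictly between, all contrasts strong
  add <- marker_trait_test(make_groups(rnorm(n, 2, 1), rnorm(n, 6, 1),
                                       rnorm(n, 11, 1)))
  expect_equal(as.character(classify_locus_effect(add)), "additive_major")
  # donor increases the trait: enhancer
  enh <- marker_trait_test(make_groups(rnorm(n, 14, 1), rnorm(n, 14, 1),
                                       rnorm(n, 11, 1)))
  expect_equal(as.character(classify_locus_effect(enh)), "enhancer")
  # donor decreases but het is donor-like: suppressor, not additive
  sup <- marker_trait_test(make_groups(rnorm(n, 2, 1), rnorm(n, 2.1, 1),
                                       rnorm(n, 11, 1)))
  expect_equal(as.character(classify_locus_effect(sup)), "suppressor")
  # same distribution in all groups: none
  none <- marker_trait_test(make_groups(rnorm(n, 8, 1), rnorm(n, 8, 1),
                                        rnorm(n, 8, 1)))
  expect_equal(as.character(classify_locus_effect(none)), "none")
  # untestable homozygote contrast: none, with a reason attached
  unt <- marker_trait_test(make_groups(c(1, 2), rnorm(n, 6, 1),
                                       rnorm(n, 11, 1)))
  call <- classify_locus_effect(unt)
  expect_equal(as.character(call), "none")
  expect_match(attr(call, "reason"), "untestable")
})

test_that("a planted additive major locus is recovered in simulated F2s", {
  # single additive locus, delta = 2.5 per donor copy, sigma = 1.5, n = 169
  genome <- sim_genome(1, 2e6, 5e5)
  model <- causal_model(data.frame(locus = "V", chrom = "A01", pos = 1e6,
                                   role = "additive_major", effect = -2.5),
                        baseline_fuzz = 11, noise_sd = 1.5)
  calls <- vapply(1:25, function(s) {
    f2 <- simulate_f2(genome, model, n = 169, seed = 5000 + s)
    res <- marker_trait_test(group_phenotype_by_genotype(
      f2$genotypes, f2$causal_markers[["V"]], f2$phenotypes))
    as.character(classify_locus_effect(res))
  }, character(1))
  expect_gte(mean(calls == "additive_major"), 0.95)
})
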