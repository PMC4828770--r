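test_that("heterozygosity and private alleles match direct arithmetic", {
  # one locus, one group of two A/G heterozygotes: Ho = 1, p = 0.5,
  # unbiased He = 2 * 0.25 * (4/3) = 2/3; second group fixed A/A
  gm <- make_geno(list(L1 = c("A/G", "A/G", "A/A", "A/A")),
                  c("g1", "g2", "h1", "h2"))
  pm <- popmap_of(G = c("g1", "g2"), H = c("h1", "h2"))
  div <- diversity_table(gm, pm)
  g <- div[div$group == "G", ]
  expect_equal(g$ho, 1)
  expect_equal(g$he, 2 * 0.25 * (4 / 3))
  # G is allele at L1 observed only in group G: one private allele there,
  # zero in H (A occurs in both groups)
  expect_equal(div$priv[div$group == "G"], 1)
  expect_equal(div$priv[div$group == "H"], 0)
  h <- div[div$group == "H", ]
  expect_equal(h$ho, 0)
  expect_equal(h$he, 0)
})

test_that("rarefaction at full depth returns the raw allele count", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 60, n_p1 = 3, n_hybrid = 3, n_p3 = 3, n_out = 3, seed = 5))
  div <- diversity_table(sim$genotypes, sim$popmap, rarefaction_n = 6)
  expect_equal(div$ar, div$k, tolerance = 1e-12)
  expect_true(all(div$ar >= 1))
  expect_true(all(div$k >= 1 & div$k <= 2))
  expect_error(diversity_table(sim$genotypes, sim$popmap, rarefaction_n = 1),
               ">= 2")
  expect_error(diversity_table(sim$genotypes, sim$popmap, rarefaction_n = 8),
               "smallest group")
})

test_that("statistics are invariant under allele relabelling", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 40, n_p1 = 3, n_hybrid = 3, n_p3 = 3, n_out = 2, seed = 6))
  gm <- sim$genotypes
  # swap nucleotide alphabet: A<->T, C<->G everywhere
  swap <- c(A = "T", T = "A", C = "G", G = "C")
  gm2 <- as_geno_tbl(
    data.frame(locus = gm$locus, individual = gm$individual,
               a1 = unname(swap[gm$a1]), a2 = unname(swap[gm$a2])),
    locus_ids = locus_ids(gm), individual_ids = individual_ids(gm))
  d1 <- diversity_table(gm, sim$popmap)
  d2 <- diversity_table(gm2, sim$popmap)
  expect_equal(d1, d2)
  f1 <- pairwise_fst(gm, sim$popmap, n_perm = 19, seed = 3)
  f2 <- pairwise_fst(gm2, sim$popmap, n_perm = 19, seed = 3)
  expect_equal(tidy(f1), tidy(f2))
})

test_that("Weir-Cockerham theta matches the hand-computed toy value", {
  toy <- wc_toy()
  fst <- pairwise_fst(toy$gm, toy$pm, n_perm = 99, seed = 1)
  expect_equal(fst$fst, toy$theta, tolerance = 1e-12)
})

test_that("Fst endpoints behave: identity, fixation, monomorphic pair", {
  # identical genotype compositions: no differentiation signal (the tiny
  # two-individual groups make the unbiased estimator go negative, never
  # positive) and permutation p ~ 1
  gm <- make_geno(list(
    L1 = c("A/G", "A/A", "A/G", "A/A"),
    L2 = c("C/C", "C/T", "C/C", "C/T"),
    L3 = c("G/T", "T/T", "G/T", "T/T")
  ), c("x1", "x2", "y1", "y2"))
  pm <- popmap_of(X = c("x1", "x2"), Y = c("y1", "y2"))
  fst <- pairwise_fst(gm, pm, n_perm = 99, seed = 2)
  expect_lte(fst$fst, 0)
  expect_gt(fst$p_value, 0.5)

  # groups fixed for alternate alleles at every locus: theta = 1
  gm2 <- make_geno(list(
    L1 = c("A/A", "A/A", "G/G", "G/G"),
    L2 = c("C/C", "C/C", "T/T", "T/T")
  ), c("x1", "x2", "y1", "y2"))
  fst2 <- pairwise_fst(gm2, pm, n_perm = 19, seed = 2)
  expect_equal(fst2$fst, 1)

  # pair monomorphic at every locus: NaN with warning (needs a third
  # group to keep the loci polymorphic overall)
  gm3 <- make_geno(list(
    L1 = c("A/A", "A/A", "A/A", "A/A", "A/G", "G/G")
  ), c("x1", "x2", "y1", "y2", "z1", "z2"))
  pm3 <- popmap_of(X = c("x1", "x2"), Y = c("y1", "y2"), Z = c("z1", "z2"))
  expect_warning(fst3 <- pairwise_fst(gm3, pm3, n_perm = 9, seed = 1),
                 "monomorphic")
  expect_true(is.nan(fst3$fst[fst3$group1 == "X" & fst3$group2 == "Y"]))
})

test_that("Fst is deterministic for a fixed seed and label-permutation of a
           homogeneous population centres near zero", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 80, n_p1 = 4, n_hybrid = 4, n_p3 = 4, n_out = 2, seed = 7))
  f1 <- pairwise_fst(sim$genotypes, sim$popmap, n_perm = 29, seed = 11)
  f2 <- pairwise_fst(sim$genotypes, sim$popmap, n_perm = 29, seed = 11)
  expect_equal(tidy(f1), tidy(f2))

  # split one simulated panmictic group arbitrarily in two: theta ~ 0
  pm <- sim$popmap[sim$popmap$group == "P3", ]
  pm$group <- rep(c("Pa", "Pb"), each = 2)
  gmP3 <- filter_complete_biallelic(
    sim$genotypes[sim$genotypes$individual %in% pm$individual, ] |>
      as_geno_tbl(individual_ids = pm$individual))
  fh <- pairwise_fst(gmP3, pm, n_perm = 49, seed = 4)
  expect_lt(abs(fh$fst), 0.15)
  expect_gt(fh$p_value, 0.05)
})

test_that("private-allele counts never exceed the distinct allele total", {
  for (s in 1:3) {
    sim <- simulate_frequency_scenario(scenario_params(
      n_loci = 50, n_p1 = 3, n_hybrid = 3, n_p3 = 3, n_out = 2, seed = s))
    div <- diversity_table(sim$genotypes, sim$popmap)
    st <- locus_stats(sim$genotypes)
    total_pairs <- sum(st$n_alleles)
    expect_lte(sum(div$priv), total_pairs)
  }
})
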