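test_that("site-pattern counts match an independent per-site enumeration", {
  expect_equal(
    count_site_patterns("A", "G", "G", "A"),
    tibble::tibble(n_abba = 1L, n_baba = 0L, n_other = 0L))
  expect_equal(
    count_site_patterns("G", "A", "G", "A"),
    tibble::tibble(n_abba = 0L, n_baba = 1L, n_other = 0L))
  # a three-allele site is never informative
  expect_equal(count_site_patterns("A", "C", "C", "T")$n_other, 1L)

  set.seed(42)
  for (rep in 1:5) {
    hs <- replicate(4, sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                    simplify = FALSE)
    got <- count_site_patterns(hs[[1]], hs[[2]], hs[[3]], hs[[4]])
    want <- oracle_site_patterns(hs[[1]], hs[[2]], hs[[3]], hs[[4]])
    expect_equal(unlist(got), want)
  }
  expect_error(count_site_patterns("A", c("A", "G"), "A", "A"), "length")
})

test_that("D from counts handles the symmetric and degenerate cases", {
  expect_equal(d_from_counts(7, 7), 0)
  expect_equal(d_from_counts(5, 0), 1)
  expect_equal(d_from_counts(0, 5), -1)
  expect_true(is.nan(d_from_counts(0, 0)))
  expect_error(d_from_counts(-1, 2), "negative")
  # vectorized
  expect_equal(d_from_counts(c(2, 1), c(1, 1)), c(1 / 3, 0))
})

test_that("test enumeration covers the reference product and both schemes", {
  pm <- popmap_of(P1 = c("a", "b"), H = "h", P3 = c("c", "d"), O = "o")
  cfg <- quartet_config("P1", "H", "P3", "O")
  tests <- enumerate_tests(pm, cfg, "h")
  expect_equal(nrow(tests), 2 * 2 * 1 * 2)  # N1 * N3 * NO * 2 runs
  expect_setequal(unique(tests$run), 1:2)

  cfg16 <- quartet_config("P1", "H", "P3", "O",
                          allele_scheme = "all_haplotypes")
  expect_equal(nrow(enumerate_tests(pm, cfg16, "h")), 4 * 16)

  # leave-one-out: P2 drawn from a 3-member P1 group shrinks the P1 pool
  pm2 <- popmap_of(P1 = c("a", "b", "e"), H = "h", P3 = c("c", "d"), O = "o")
  ctl <- enumerate_tests(pm2, cfg, "a")
  expect_false("a" %in% ctl$p1)
  expect_equal(length(unique(ctl$p1)), 2)
  expect_error(enumerate_tests(pm, cfg, "o"), "empty")
})

test_that("a P2 identical to its P3 reference gives D = 1, no BABA sites", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 120, n_p1 = 2, n_hybrid = 1, n_p3 = 1, n_out = 1, seed = 13))
  gm <- sim$genotypes
  # clone the sole P3 reference's genotypes into the hybrid individual:
  # every test then has h3 identical to h2, which rules BABA out
  don <- gm[gm$individual == "P3_01", ]
  gm$a1[gm$individual == "H_01"] <- don$a1[match(
    gm$locus[gm$individual == "H_01"], don$locus)]
  gm$a2[gm$individual == "H_01"] <- don$a2[match(
    gm$locus[gm$individual == "H_01"], don$locus)]
  gm <- filter_complete_biallelic(gm)  # cloning can fix some loci
  cfg <- quartet_config("P1", "H", "P3", "O", controls = FALSE)
  res <- run_individual_dstat(gm, sim$popmap, cfg)
  expect_true(all(res$tests$n_baba == 0))
  ok <- !is.nan(res$tests$d)
  expect_gt(sum(ok), 0)
  expect_true(all(res$tests$d[ok] == 1))
})

test_that("swapping the P1 and P2 roles negates every D exactly", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 150, n_p1 = 2, n_hybrid = 2, n_p3 = 2, n_out = 1,
    f = 0.3, seed = 14))
  pm <- sim$popmap
  fwd <- run_individual_dstat(sim$genotypes, pm,
                              quartet_config("P1", "H", "P3", "O",
                                             controls = FALSE))
  rev <- run_individual_dstat(sim$genotypes, pm,
                              quartet_config("H", "P1", "P3", "O",
                                             controls = FALSE))
  key <- function(x) paste(x$p2, x$p1, x$p3, x$outgroup, x$run)
  m <- match(paste(fwd$tests$p1, fwd$tests$p2, fwd$tests$p3,
                   fwd$tests$outgroup, fwd$tests$run), key(rev$tests))
  expect_false(anyNA(m))
  expect_equal(fwd$tests$n_abba, rev$tests$n_baba[m])
  expect_equal(fwd$tests$d, -rev$tests$d[m])
  # count conservation: informative sites never exceed the locus count
  expect_true(all(fwd$tests$n_abba + fwd$tests$n_baba <= 150))
})

test_that("summaries average with equal individual weight and report f
           against the maximal-control excess", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 400, n_p1 = 3, n_hybrid = 3, n_p3 = 3, n_out = 2,
    f = 0.25, seed = 15))
  res <- run_individual_dstat(sim$genotypes, sim$popmap,
                              quartet_config("P1", "H", "P3", "O"))
  ind <- res$individuals
  taxa <- res$taxa
  for (g in unique(taxa$p2_group)) {
    expect_equal(taxa$mean_d[taxa$p2_group == g],
                 mean(ind$mean_d[ind$p2_group == g]))
  }
  # N per individual under the paired scheme (leave-one-out for controls)
  expect_true(all(ind$n_tests[ind$p2_group == "H"] == 3 * 3 * 2 * 2))
  expect_true(all(ind$n_tests[ind$p2_group == "P1"] == 2 * 3 * 2 * 2))
  # maximal-control taxon recovers f = 100 % by construction
  expect_equal(taxa$f_pct[!is.na(taxa$control) & taxa$control == "max"], 100)
  # admixture_fraction on the tests tibble agrees with the merged summary
  af <- admixture_fraction(res$tests)
  expect_equal(af$s_max, res$s_max)
  m <- match(ind$p2, af$individuals$p2)
  expect_equal(ind$f_pct, af$individuals$f_pct[m])
  # a taxon with zero mean excess has f = 0; S_i = S_max gives 100
  expect_error(admixture_fraction(res$tests[is.na(res$tests$control), ]),
               "control")
})

test_that("reference-bias deviations are test-count weighted around zero
           and a doctored reference individual is flagged", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 500, n_p1 = 4, n_hybrid = 4, n_p3 = 4, n_out = 2,
    f = 0.2, seed = 16))
  res <- run_individual_dstat(sim$genotypes, sim$popmap,
                              quartet_config("P1", "H", "P3", "O",
                                             controls = FALSE))
  ba <- reference_bias_analysis(res$tests)
  for (r in unique(ba$effects$role)) {
    e <- ba$effects[ba$effects$role == r, ]
    expect_equal(sum(e$n_tests * e$deviation), 0, tolerance = 1e-9)
  }
  expect_true(all(c("p1", "p3", "outgroup") %in% ba$role_tests$role))
  expect_s3_class(ba$role_tests, "tbl_df")
  kb <- reference_bias_analysis(res$tests, method = "kruskal")
  expect_equal(kb$role_tests$method, rep("kruskal", 3))

  # give one P1 individual a 30 % P3 mosaic: an introgressed P1 reference
  # matches P3 at extra sites, inflating BABA, so its tests show the
  # largest (downward) deviation in the role and it is flagged
  gm <- sim$genotypes
  don <- gm[gm$individual == "P3_01", ]
  tgt <- gm$individual == "P1_01"
  set.seed(99)
  swap_loci <- sample(locus_ids(gm), 150)
  sel <- tgt & gm$locus %in% swap_loci
  gm$a1[sel] <- don$a1[match(gm$locus[sel], don$locus)]
  gm$a2[sel] <- don$a2[match(gm$locus[sel], don$locus)]
  gm <- filter_complete_biallelic(gm)
  res2 <- run_individual_dstat(gm, sim$popmap,
                               quartet_config("P1", "H", "P3", "O",
                                              controls = FALSE))
  ba2 <- reference_bias_analysis(res2$tests)
  p1eff <- ba2$effects[ba2$effects$role == "p1", ]
  worst <- which.max(abs(p1eff$deviation))
  expect_equal(p1eff$id[worst], "P1_01")
  expect_lt(p1eff$deviation[worst], 0)
  expect_true(p1eff$outlier[worst])

  solo <- res$tests[res$tests$outgroup == res$tests$outgroup[1], ]
  expect_warning(reference_bias_analysis(solo), "single individual")
})

test_that("tidy, glance and autoplot expose the result object", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 150, n_p1 = 2, n_hybrid = 2, n_p3 = 2, n_out = 1,
    f = 0.3, seed = 17))
  res <- run_individual_dstat(sim$genotypes, sim$popmap,
                              quartet_config("P1", "H", "P3", "O"))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res, "taxa")), 3)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true(is.finite(g$mean_d))
  expect_s3_class(autoplot(res), "ggplot")
})
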