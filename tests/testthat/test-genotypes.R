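test_that("TSV parsing preserves missing calls and ordering", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "locus\tindividual\tallele1\tallele2",
    "L1\ti1\tA\tG",
    "L1\ti2\t.\t.",
    "L2\ti1\tC\tC",
    "L2\ti2\tC\tT",
    "L3\ti1\tT\tT",
    "L3\ti2\tT\tA"
  ), path)
  gm <- read_genotypes(path, "tsv")
  expect_equal(locus_ids(gm), c("L1", "L2", "L3"))
  expect_equal(individual_ids(gm), c("i1", "i2"))
  expect_equal(sum(is.na(gm$a1)), 1)
  st <- locus_stats(gm)
  expect_equal(st$n_missing, c(1, 0, 0))
  expect_equal(st$biallelic, c(TRUE, TRUE, TRUE))
})

test_that("duplicate individual assignments are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual\tgroup", "i1\tA", "i1\tB"), path)
  expect_error(read_popmap(path), "more than one group")
  expect_error(
    as_geno_tbl(data.frame(locus = c("L1", "L1"),
                           individual = c("i1", "i1"),
                           a1 = c("A", "A"), a2 = c("A", "G"))),
    "duplicate"
  )
})

test_that("VCF round trip preserves calls, flags multi-allelic sites", {
  sim <- simulate_frequency_scenario(scenario_params(
    n_loci = 30, n_p1 = 2, n_hybrid = 2, n_p3 = 2, n_out = 1, seed = 11))
  gm <- sim$genotypes
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, vcf, "vcf")
  write_genotypes(gm, tsv, "tsv")
  expect_identical(as.data.frame(read_genotypes(vcf, "vcf")),
                   as.data.frame(gm))
  expect_identical(as.data.frame(read_genotypes(tsv, "tsv")),
                   as.data.frame(gm))

  # a triallelic record is read, retained and flagged, not dropped
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "rad1\t1\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2",
    "rad2\t1\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t./."
  ), path)
  gm2 <- read_genotypes(path, "vcf")
  st <- locus_stats(gm2)
  expect_equal(nrow(st), 2)
  expect_false(st$biallelic[st$locus == "rad1"])
  expect_equal(st$n_alleles[st$locus == "rad1"], 3)
  expect_equal(sum(is.na(gm2$a1)), 1)
})

test_that("complete-biallelic filter keeps exactly the eligible loci", {
  gm <- make_geno(list(
    L1 = c("A/G", "A/A", "G/G"),   # keep
    L2 = c("A/G", "./.", "G/G"),   # missing call
    L3 = c("C/T", "C/C", "T/T"),   # keep
    L4 = c("A/G", "A/T", "G/G"),   # triallelic
    L5 = c("C/C", "./.", "C/C")    # missing + monomorphic
  ), c("i1", "i2", "i3"))
  out <- filter_complete_biallelic(gm)
  expect_equal(locus_ids(out), c("L1", "L3"))
  # idempotent
  expect_identical(as.data.frame(filter_complete_biallelic(out)),
                   as.data.frame(out))
  st <- locus_stats(out)
  expect_true(all(st$n_alleles == 2 & st$n_missing == 0))
  # identity on an already-clean matrix
  clean <- make_geno(list(L1 = c("A/G", "G/G"), L2 = c("C/C", "C/T")),
                     c("i1", "i2"))
  expect_identical(as.data.frame(filter_complete_biallelic(clean)),
                   as.data.frame(clean))
  expect_warning(
    filter_complete_biallelic(
      make_geno(list(L1 = c("A/A", "A/A")), c("i1", "i2"))),
    "no complete biallelic"
  )
})

test_that("haplotype split follows storage order and reconstructs calls", {
  gm <- make_geno(list(L1 = c("A/G", "A/A"), L2 = c("A/A", "C/C")),
                  c("i1", "i2"))
  hp <- split_haplotypes(gm, "i1")
  expect_equal(hp$hapA, c("A", "A"))
  expect_equal(hp$hapB, c("G", "A"))
  # fully homozygous individual: identical haplotypes
  hp2 <- split_haplotypes(gm, "i2")
  expect_identical(hp2$hapA, hp2$hapB)
  # site-wise recombination recovers the stored genotype calls
  for (ind in c("i1", "i2")) {
    hp <- split_haplotypes(gm, ind)
    sub <- gm[gm$individual == ind, ]
    sub <- sub[match(hp$locus, sub$locus), ]
    expect_equal(hp$hapA, sub$a1)
    expect_equal(hp$hapB, sub$a2)
  }
  miss <- make_geno(list(L1 = c("A/G", "./.")), c("i1", "i2"))
  expect_error(split_haplotypes(miss, "i2"), "missing call")
})

test_that("one-SNP-per-RAD-locus mode keeps the first site per locus id", {
  gm <- make_geno(list(
    "r1:1" = c("A/G", "G/G"), "r1:7" = c("C/T", "C/C"),
    "r2:3" = c("A/A", "A/T")
  ), c("i1", "i2"))
  out <- filter_one_snp_per_locus(gm)
  expect_equal(locus_ids(out), c("r1:1", "r2:3"))
})
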