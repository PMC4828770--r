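#' Per-group diversity statistics
#'
#' Computes, for each group in the population map: mean number of alleles
#' per locus (K), rarefied allelic richness (AR), the number of private
#' alleles (Priv: (locus, allele) pairs observed in exactly one group),
#' mean observed heterozygosity (Ho) and mean unbiased expected
#' heterozygosity (He), each mean accompanied by its across-locus SD.
#'
#' Allelic richness uses hypergeometric rarefaction to a common number of
#' gene copies `rarefaction_n`: the expected number of distinct alleles in a
#' draw of `rarefaction_n` copies from the group's `2n` sampled copies,
#' `sum_a (1 - C(2n - c_a, g) / C(2n, g))`. Expected heterozygosity uses the
#' small-sample correction `2p(1-p) * 2n/(2n-1)`.
#'
#' @param gm A complete biallelic genotype table
#'   (see [filter_complete_biallelic()]).
#' @param pm Population map (`individual`, `group`).
#' @param rarefaction_n Number of gene copies to rarefy to; default
#'   `2 * min(group size)`, the largest depth every group supports. Must be
#'   at least 2 and no larger than the default.
#' @return A tibble with one row per group: `group`, `n`, `k`, `k_sd`,
#'   `ar`, `ar_sd`, `priv`, `ho`, `ho_sd`, `he`, `he_sd`.
#' @examples
#' sim <- simulate_frequency_scenario(scenario_params(n_loci = 50, seed = 1))
#' diversity_table(sim$genotypes, sim$popmap)
#' @export
diversity_table <- function(gm, pm, rarefaction_n = NULL) {
  pm <- validate_popmap(gm, pm)
  rec <- recode_biallelic(gm)
  groups <- unique(pm$group)
  sizes <- vapply(groups, function(g) sum(pm$group == g), integer(1))
  if (any(sizes == 0)) stop("empty group")
  max_g <- 2L * min(sizes)
  if (is.null(rarefaction_n)) rarefaction_n <- max_g
  if (rarefaction_n < 2) stop("rarefaction_n must be >= 2")
  if (rarefaction_n > max_g) {
    stop("rarefaction_n exceeds 2 * smallest group size (", max_g, ")")
  }

  dos <- rec$hapA + rec$hapB            # loci x individuals count of allele 1
  het <- rec$hapA != rec$hapB
  inds <- individual_ids(gm)

  # per-group per-locus counts of the two alleles
  c1 <- vapply(groups, function(g) {
    rowSums(dos[, inds %in% pm$individual[pm$group == g], drop = FALSE])
  }, numeric(nrow(dos)))
  c1 <- matrix(c1, nrow = nrow(dos))  # keep matrix shape at one locus
  n2 <- matrix(rep(2 * sizes, each = nrow(dos)), nrow(dos))  # gene copies
  c0 <- n2 - c1
  pres0 <- c0 > 0
  pres1 <- c1 > 0
  priv0 <- pres0 & (rowSums(pres0) == 1)
  priv1 <- pres1 & (rowSums(pres1) == 1)

  rows <- lapply(seq_along(groups), function(j) {
    g <- groups[j]
    n <- sizes[j]
    cols <- inds %in% pm$individual[pm$group == g]
    k_l <- pres0[, j] + pres1[, j]
    ar_l <- rarefied_alleles(c0[, j], 2 * n, rarefaction_n) +
      rarefied_alleles(c1[, j], 2 * n, rarefaction_n)
    ho_l <- rowMeans(het[, cols, drop = FALSE])
    p <- c1[, j] / (2 * n)
    he_l <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
    tibble::tibble(
      group = g, n = n,
      k = mean(k_l), k_sd = stats::sd(k_l),
      ar = mean(ar_l), ar_sd = stats::sd(ar_l),
      priv = sum(priv0[, j]) + sum(priv1[, j]),
      ho = mean(ho_l), ho_sd = stats::sd(ho_l),
      he = mean(he_l), he_sd = stats::sd(he_l)
    )
  })
  dplyr::bind_rows(rows)
}

# expected contribution of an allele with count c (of n_tot copies) to the
# rarefied allele count at depth g: 1 - C(n_tot - c, g) / C(n_tot, g)
rarefied_alleles <- function(c_allele, n_tot, g) {
  out <- 1 - exp(lchoose(n_tot - c_allele, g) - lchoose(n_tot, g))
  out[n_tot - c_allele < g] <- 1
  out[c_allele == 0] <- 0
  out
}

#' Pairwise Weir-Cockerham Fst with permutation test
#'
#' Multilocus Weir & Cockerham (1984) theta for every pair of groups: the
#' ratio of the among-population variance component summed over loci to the
#' summed total (a / (a + b + c)). Significance is assessed by permuting
#' individuals (both alleles move together) between the two groups:
#' the p-value is the proportion of permuted datasets with Fst at least as
#' large as observed.
#'
#' @param gm A complete biallelic genotype table.
#' @param pm Population map.
#' @param n_perm Number of label permutations per pair.
#' @param seed Integer RNG seed; results are deterministic given the seed.
#' @return A tibble of class `fst_tbl` with columns `group1`, `group2`,
#'   `fst`, `p_value`, plus attributes `n_perm` and `seed`. A pair of groups
#'   monomorphic at every locus has undefined Fst (`NaN`, with a warning).
#' @examples
#' sim <- simulate_frequency_scenario(scenario_params(n_loci = 100, seed = 1))
#' pairwise_fst(sim$genotypes, sim$popmap, n_perm = 99, seed = 1)
#' @export
pairwise_fst <- function(gm, pm, n_perm = 1000, seed = 1) {
  pm <- validate_popmap(gm, pm)
  rec <- recode_biallelic(gm)
  dos <- rec$hapA + rec$hapB
  het <- rec$hapA != rec$hapB
  inds <- individual_ids(gm)
  groups <- unique(pm$group)
  sizes <- vapply(groups, function(g) sum(pm$group == g), integer(1))
  if (any(sizes < 2)) stop("pairwise_fst needs >= 2 individuals per group")

  pairs <- utils::combn(groups, 2)
  rows <- with_seed(seed, {
    lapply(seq_len(ncol(pairs)), function(k) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      i1 <- which(inds %in% pm$individual[pm$group == g1])
      i2 <- which(inds %in% pm$individual[pm$group == g2])
      obs <- wc_theta(dos, het, i1, i2)
      if (is.nan(obs)) {
        warning("Fst undefined for monomorphic pair ", g1, " / ", g2)
        return(tibble::tibble(group1 = g1, group2 = g2,
                              fst = NaN, p_value = NA_real_))
      }
      both <- c(i1, i2)
      n1 <- length(i1)
      perm <- vapply(seq_len(n_perm), function(r) {
        sh <- sample(both)
        wc_theta(dos, het, sh[seq_len(n1)], sh[-seq_len(n1)])
      }, numeric(1))
      tibble::tibble(group1 = g1, group2 = g2, fst = obs,
                     p_value = mean(perm >= obs, na.rm = TRUE))
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, n_perm = n_perm, seed = seed,
            class = c("fst_tbl", class(tibble::tibble())))
}

# multilocus WC84 theta for two groups given dosage / heterozygosity
# matrices (loci x individuals) and the two column index sets
wc_theta <- function(dos, het, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  p1 <- rowSums(dos[, i1, drop = FALSE]) / (2 * n1)
  p2 <- rowSums(dos[, i2, drop = FALSE]) / (2 * n2)
  h1 <- rowMeans(het[, i1, drop = FALSE])
  h2 <- rowMeans(het[, i2, drop = FALSE])
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  den <- sum(a + b + cc)
  if (den == 0) return(NaN)
  sum(a) / den
}

#' @export
tidy.fst_tbl <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("group1", "group2", "fst", "p_value")])
}

#' Fst tibble as a symmetric matrix
#'
#' @param x An `fst_tbl` from [pairwise_fst()].
#' @return A symmetric numeric matrix with `NA` diagonal.
#' @export
fst_matrix <- function(x) {
  groups <- unique(c(x$group1, x$group2))
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(nrow(x))) {
    m[x$group1[i], x$group2[i]] <- x$fst[i]
    m[x$group2[i], x$group1[i]] <- x$fst[i]
  }
  m
}
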