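#' Population-allele-frequency D statistic
#'
#' Computes Patterson's D from per-group derived-allele frequencies:
#' `D = sum_l[(1-p1)p2p3(1-p4) - p1(1-p2)p3(1-p4)] /
#'      sum_l[(1-p1)p2p3(1-p4) + p1(1-p2)p3(1-p4)]`,
#' where `p1..p4` are the derived-allele frequencies in the P1, P2, P3 and
#' outgroup samples. The derived allele at each locus is the least frequent
#' allele among the outgroup's gene copies; an exact 0.5 tie is broken by
#' the global minor allele across the whole matrix, then by lexicographic
#' order, so the rule is fully deterministic. With one haploid sequence per
#' group this reduces exactly to the site-pattern D of
#' [count_site_patterns()] + [d_from_counts()].
#'
#' @param gm A complete biallelic genotype table.
#' @param pm Population map.
#' @param cfg A [quartet_config()] providing the P1, P3 and outgroup
#'   groups.
#' @param p2_group Group evaluated as P2.
#' @return A `pop_dstat` list: `d`, `freqs` (per-locus derived allele and
#'   frequencies `p1..p4` with gene-copy counts `n1..n4`), and the role
#'   assignment. Bootstrap fields are filled by
#'   [bootstrap_population_d()]. `D` is `NaN` (with a warning) when no
#'   locus is informative.
#' @examples
#' sim <- simulate_frequency_scenario(scenario_params(
#'   n_loci = 300, f = 0.3, seed = 1))
#' cfg <- quartet_config("P1", "H", "P3", "O")
#' pd <- population_dstat(sim$genotypes, sim$popmap, cfg, "H")
#' pd <- bootstrap_population_d(pd, n_reps = 100, seed = 1)
#' glance(pd)
#' @export
population_dstat <- function(gm, pm, cfg, p2_group) {
  stopifnot(inherits(cfg, "quartet_config"))
  pm <- validate_popmap(gm, pm)
  rec <- recode_biallelic(gm)
  dos <- rec$hapA + rec$hapB
  dos <- matrix(dos, nrow = nrow(rec$hapA))
  inds <- individual_ids(gm)
  groups <- c(p1 = cfg$p1, p2 = p2_group, p3 = cfg$p3, outgroup = cfg$outgroup)
  cols <- lapply(groups, function(g) which(inds %in% group_members(pm, g)))
  n_cop <- vapply(cols, function(ix) 2L * length(ix), integer(1))
  freq1 <- vapply(cols, function(ix) {
    rowSums(dos[, ix, drop = FALSE]) / (2 * length(ix))
  }, numeric(nrow(dos)))
  freq1 <- matrix(freq1, nrow = nrow(dos))

  # derived allele: least frequent in the outgroup; tie -> global minor,
  # then lexicographic (allele0 is the lexicographically first label)
  glob1 <- rowSums(dos) / (2 * length(inds))
  derived_is_1 <- freq1[, 4] < 0.5 |
    (freq1[, 4] == 0.5 & (glob1 < 0.5))
  p <- ifelse(matrix(derived_is_1, nrow(dos), 4), freq1, 1 - freq1)
  freqs <- tibble::tibble(
    locus = locus_ids(gm),
    derived_allele = ifelse(derived_is_1, rec$alleles$allele1,
                            rec$alleles$allele0),
    p1 = p[, 1], p2 = p[, 2], p3 = p[, 3], p4 = p[, 4],
    n1 = n_cop[1], n2 = n_cop[2], n3 = n_cop[3], n4 = n_cop[4]
  )
  d <- pop_d_from_freqs(p[, 1], p[, 2], p[, 3], p[, 4])
  if (is.nan(d)) warning("no informative locus; population D undefined")
  structure(
    list(d = d, freqs = freqs, groups = as.list(groups),
         replicates = NULL, range = NULL, significant = NA,
         n_reps = NULL, seed = NULL),
    class = "pop_dstat"
  )
}

# Patterson's D from derived-allele frequency vectors
pop_d_from_freqs <- function(p1, p2, p3, p4) {
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  den <- sum(abba + baba)
  if (den == 0) return(NaN)
  sum(abba - baba) / den
}

#' Binomial bootstrap of the population D statistic
#'
#' For each replicate, the derived-allele count of every locus x population
#' cell is redrawn from a binomial distribution with size equal to that
#' population's sampled gene copies and probability equal to the observed
#' derived frequency; D is recomputed from the resampled frequencies. The
#' min-max range of replicate D values assesses significance: the
#' statistic is called significant when the range excludes zero.
#'
#' @param result A `pop_dstat` from [population_dstat()].
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer RNG seed; replicates are deterministic given it.
#' @return The `pop_dstat` with `replicates`, `range` (min, max),
#'   `significant`, `n_reps` and `seed` filled in.
#' @export
bootstrap_population_d <- function(result, n_reps = 100, seed = 1) {
  stopifnot(inherits(result, "pop_dstat"))
  fr <- result$freqs
  n <- c(fr$n1[1], fr$n2[1], fr$n3[1], fr$n4[1])
  p <- cbind(fr$p1, fr$p2, fr$p3, fr$p4)
  L <- nrow(p)
  reps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      ps <- vapply(1:4, function(j) {
        stats::rbinom(L, n[j], p[, j]) / n[j]
      }, numeric(L))
      ps <- matrix(ps, nrow = L)
      pop_d_from_freqs(ps[, 1], ps[, 2], ps[, 3], ps[, 4])
    }, numeric(1))
  })
  result$replicates <- reps
  result$range <- range(reps, na.rm = TRUE)
  result$significant <- result$range[1] > 0 || result$range[2] < 0
  result$n_reps <- n_reps
  result$seed <- seed
  result
}

#' @export
print.pop_dstat <- function(x, ...) {
  cat(sprintf("# Population-frequency D: %.4f (%d loci)\n",
              x$d, nrow(x$freqs)))
  if (!is.null(x$range)) {
    cat(sprintf("  bootstrap range (%d reps): %.4f - %.4f; %s\n",
                x$n_reps, x$range[1], x$range[2],
                if (isTRUE(x$significant)) "excludes 0" else "includes 0"))
  }
  invisible(x)
}

#' @export
tidy.pop_dstat <- function(x, ...) x$freqs

#' @export
glance.pop_dstat <- function(x, ...) {
  tibble::tibble(
    d = x$d,
    n_loci = nrow(x$freqs),
    n_reps = x$n_reps %||% NA_integer_,
    boot_min = if (is.null(x$range)) NA_real_ else x$range[1],
    boot_max = if (is.null(x$range)) NA_real_ else x$range[2],
    significant = x$significant
  )
}
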