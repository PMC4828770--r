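#' Count ABBA / BABA site patterns in a sequence quartet
#'
#' Over four equal-length haplotype vectors arranged on the species tree
#' (((P1,P2),P3),Outgroup), a site is ABBA when P1 matches the outgroup and
#' P2 matches P3 for a different allele (`h1 = h4 != h2 = h3`) and BABA when
#' P2 matches the outgroup and P1 matches P3 (`h2 = h4 != h1 = h3`); only
#' sites with exactly two distinct alleles among the four sequences qualify
#' (either condition implies this). Everything else counts as "other".
#'
#' @param h1,h2,h3,h4 Single-allele vectors over the same loci for the P1,
#'   P2, P3 and outgroup sequences.
#' @return A one-row tibble: `n_abba`, `n_baba`, `n_other`.
#' @examples
#' count_site_patterns(c("A", "G"), c("G", "A"), c("G", "G"), c("A", "A"))
#' @export
count_site_patterns <- function(h1, h2, h3, h4) {
  n <- length(h1)
  if (length(h2) != n || length(h3) != n || length(h4) != n) {
    stop("haplotype vectors differ in length")
  }
  if (anyNA(c(h1, h2, h3, h4))) stop("missing allele in quartet")
  abba <- h1 == h4 & h2 == h3 & h1 != h2
  baba <- h2 == h4 & h1 == h3 & h1 != h2
  tibble::tibble(n_abba = sum(abba), n_baba = sum(baba),
                 n_other = n - sum(abba) - sum(baba))
}

#' Patterson's D from pattern counts
#'
#' `D = (nABBA - nBABA) / (nABBA + nBABA)`. Under incomplete lineage
#' sorting alone the two discordant patterns are equally frequent and D is
#' near 0; gene flow from P3 into P2 inflates ABBA and pushes D toward 1.
#' Counts need not be integers (means of counts are valid inputs).
#'
#' @param n_abba,n_baba Non-negative counts (vectorized).
#' @return Numeric vector of D; `NaN` where both counts are zero.
#' @examples
#' d_from_counts(16.63, 5.56)
#' @export
d_from_counts <- function(n_abba, n_baba) {
  if (any(n_abba < 0 | n_baba < 0, na.rm = TRUE)) stop("negative count")
  tot <- n_abba + n_baba
  ifelse(tot == 0, NaN, (n_abba - n_baba) / tot)
}

#' Four-taxon test configuration
#'
#' Assigns population-map groups to the roles of the test: P1 (sister of
#' the putative hybrid, no gene flow assumed), one or more P2 candidate
#' groups (putative hybrids), P3 (donor) and the outgroup. With
#' `controls = TRUE`, [run_individual_dstat()] additionally evaluates every
#' P1-group member as P2 (zero-gene-flow control) and every P3-group member
#' as P2 (maximal-gene-flow control, also the denominator of the admixture
#' proportion f); a control individual is removed from its own reference
#' pool (leave-one-out), so no individual ever serves as its own reference.
#'
#' @param p1,p3,outgroup Single group labels.
#' @param p2 Character vector of P2 candidate group labels.
#' @param allele_scheme `"paired"` (default): each reference combination is
#'   run twice, once on the first-stored allele of all four individuals and
#'   once on the second. `"all_haplotypes"`: all 16 haplotype assignments
#'   per combination.
#' @param controls Include the two control configurations.
#' @return A `quartet_config` list.
#' @export
quartet_config <- function(p1, p2, p3, outgroup,
                           allele_scheme = c("paired", "all_haplotypes"),
                           controls = TRUE) {
  allele_scheme <- match.arg(allele_scheme)
  roles <- c(p1, p3, outgroup)
  if (anyDuplicated(c(roles, p2)) > 0) stop("role groups must be disjoint")
  structure(list(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
                 allele_scheme = allele_scheme, controls = controls),
            class = "quartet_config")
}

# haplotype letters (P1, P2, P3, O) for a run index under a scheme
run_haplotypes <- function(run, allele_scheme) {
  if (allele_scheme == "paired") {
    rep(c("A", "B")[run], 4)
  } else {
    c("A", "B")[1 + ((run - 1) %/% c(8L, 4L, 2L, 1L)) %% 2L]
  }
}

#' Enumerate the tests for one P2 individual
#'
#' The Cartesian product of all P1 x P3 x outgroup reference individuals
#' and all haplotype runs of the configured allele scheme. When the P2
#' individual itself belongs to a reference group (control tests) it is
#' left out of that group's pool.
#'
#' @param pm Population map.
#' @param cfg A [quartet_config()].
#' @param p2_individual Individual id tested as P2.
#' @return A tibble with columns `p2`, `p1`, `p3`, `outgroup`, `run`.
#' @export
enumerate_tests <- function(pm, cfg, p2_individual) {
  pool <- function(group) {
    m <- setdiff(group_members(pm, group), p2_individual)
    if (length(m) == 0) {
      stop("empty ", group, " pool after leaving out ", p2_individual)
    }
    m
  }
  n_runs <- if (cfg$allele_scheme == "paired") 2L else 16L
  grid <- tidyr::expand_grid(
    p1 = pool(cfg$p1), p3 = pool(cfg$p3), outgroup = pool(cfg$outgroup),
    run = seq_len(n_runs)
  )
  dplyr::bind_cols(tibble::tibble(p2 = rep(p2_individual, nrow(grid))), grid)
}

#' Exhaustive individual-based ABBA/BABA tests
#'
#' Runs every enumerated quartet test for every P2 candidate individual —
#' all combinations of reference individuals, each combination run on both
#' alleles of the diploid samples so heterozygous sites contribute rather
#' than being discarded — plus, when configured, the zero- and
#' maximal-gene-flow controls. Tests with no informative site (`D = NaN`)
#' are excluded from averages and their count logged in the summaries.
#'
#' @param gm A complete biallelic genotype table.
#' @param pm Population map.
#' @param cfg A [quartet_config()].
#' @return A `dstat_result` list: `tests` (one row per quartet test with
#'   `n_abba`, `n_baba`, `d`, `s = n_abba - n_baba`), `individuals`
#'   (per-P2-individual means and SDs, plus `f_pct` when the maximal
#'   control ran), `taxa` (per-P2-group summaries; taxon means weight every
#'   member individual equally) and `s_max` (mean ABBA-BABA excess of the
#'   maximal-control tests). Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' sim <- simulate_frequency_scenario(scenario_params(
#'   n_loci = 300, n_p1 = 3, n_hybrid = 3, n_p3 = 3, n_out = 2,
#'   f = 0.3, seed = 1))
#' cfg <- quartet_config("P1", "H", "P3", "O")
#' res <- run_individual_dstat(sim$genotypes, sim$popmap, cfg)
#' glance(res)
#' @export
run_individual_dstat <- function(gm, pm, cfg) {
  stopifnot(inherits(cfg, "quartet_config"))
  pm <- validate_popmap(gm, pm)
  rec <- recode_biallelic(gm)
  inds <- individual_ids(gm)
  H <- list(A = rec$hapA, B = rec$hapB)

  candidates <- dplyr::bind_rows(
    lapply(cfg$p2, function(g) {
      tibble::tibble(individual = group_members(pm, g), group = g,
                     control = NA_character_)
    }),
    if (cfg$controls) tibble::tibble(
      individual = group_members(pm, cfg$p1), group = cfg$p1,
      control = "zero"),
    if (cfg$controls) tibble::tibble(
      individual = group_members(pm, cfg$p3), group = cfg$p3,
      control = "max")
  )

  test_rows <- vector("list", nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    p2_id <- candidates$individual[ci]
    tests <- enumerate_tests(pm, cfg, p2_id)
    tests$n_abba <- NA_integer_
    tests$n_baba <- NA_integer_
    i2 <- match(p2_id, inds)
    # vectorize over the P1 x P3 pool for each (outgroup, run) slice
    combos <- dplyr::distinct(tests[c("outgroup", "run")])
    p1_pool <- unique(tests$p1)
    p3_pool <- unique(tests$p3)
    i1 <- match(p1_pool, inds)
    i3 <- match(p3_pool, inds)
    for (k in seq_len(nrow(combos))) {
      hl <- run_haplotypes(combos$run[k], cfg$allele_scheme)
      A1 <- H[[hl[1]]][, i1, drop = FALSE]
      h2 <- H[[hl[2]]][, i2]
      A3 <- H[[hl[3]]][, i3, drop = FALSE]
      a4 <- H[[hl[4]]][, match(combos$outgroup[k], inds)]
      diff12 <- A1 != h2                       # loci x N1
      n_abba <- crossprod((A1 == a4) & diff12, A3 == h2)
      U <- diff12 & (h2 == a4)
      n_baba <- crossprod(U & (A1 == 1L), A3 == 1L) +
        crossprod(U & (A1 == 0L), A3 == 0L)
      sel <- tests$outgroup == combos$outgroup[k] & tests$run == combos$run[k]
      idx <- cbind(match(tests$p1[sel], p1_pool),
                   match(tests$p3[sel], p3_pool))
      tests$n_abba[sel] <- as.integer(n_abba[idx])
      tests$n_baba[sel] <- as.integer(n_baba[idx])
    }
    tests$p2_group <- candidates$group[ci]
    tests$control <- candidates$control[ci]
    test_rows[[ci]] <- tests
  }
  tests <- dplyr::bind_rows(test_rows)
  tests$d <- d_from_counts(tests$n_abba, tests$n_baba)
  tests$s <- tests$n_abba - tests$n_baba

  out <- structure(
    list(tests = tests, individuals = NULL, taxa = NULL,
         config = cfg, n_loci = nrow(rec$hapA), s_max = NA_real_),
    class = "dstat_result"
  )
  summarise_dstat(out)
}

# per-individual and per-taxon summaries (+ f when the max control ran)
summarise_dstat <- function(x) {
  tests <- x$tests
  ind <- dplyr::summarise(
    dplyr::group_by(tests, .data$p2_group, .data$control, p2 = .data$p2),
    n_tests = dplyr::n(),
    n_excluded = sum(is.nan(.data$d)),
    mean_d = mean(.data$d[!is.nan(.data$d)]),
    sd_d = stats::sd(.data$d[!is.nan(.data$d)]),
    mean_abba = mean(.data$n_abba), sd_abba = stats::sd(.data$n_abba),
    mean_baba = mean(.data$n_baba), sd_baba = stats::sd(.data$n_baba),
    mean_s = mean(.data$s),
    .groups = "drop"
  )
  if (isTRUE(x$config$controls)) {
    s_max <- mean(tests$s[!is.na(tests$control) & tests$control == "max"])
    if (!is.na(s_max) && s_max <= 0) {
      stop("maximal-control mean ABBA-BABA excess is non-positive (",
           signif(s_max, 3), "); admixture fraction f undefined")
    }
    ind$f_pct <- 100 * ind$mean_s / s_max
    x$s_max <- s_max
  }
  taxa <- dplyr::summarise(
    dplyr::group_by(ind, .data$p2_group, .data$control),
    n_individuals = dplyr::n(),
    n_tests = sum(.data$n_tests),
    n_excluded = sum(.data$n_excluded),
    sd_d = stats::sd(.data$mean_d),
    mean_d = mean(.data$mean_d),
    mean_abba = mean(.data$mean_abba),
    mean_baba = mean(.data$mean_baba),
    mean_s = mean(.data$mean_s),
    f_pct = if ("f_pct" %in% names(ind)) mean(.data$f_pct) else NA_real_,
    .groups = "drop"
  )
  x$individuals <- ind
  x$taxa <- taxa
  x
}

#' Admixture proportion f from ABBA-BABA excess
#'
#' Scales each P2 individual's mean ABBA-BABA excess `S = nABBA - nBABA` by
#' the mean excess observed in the maximal-gene-flow control tests (P3
#' members run as P2), pooled over all such tests: `f_i = S_i / S_max`,
#' reported as a percentage. Taxon f is the mean over member individuals.
#' This is a conservative minimum estimate of the fraction of the P2
#' genome derived from P3.
#'
#' @param tests The per-test tibble of a `dstat_result` (columns
#'   `p2`, `p2_group`, `control`, `s`).
#' @return A list with tibbles `individuals` (`p2`, `p2_group`, `f_pct`)
#'   and `taxa` (`p2_group`, `f_pct`), and the scalar `s_max`.
#' @export
admixture_fraction <- function(tests) {
  mx <- tests$s[!is.na(tests$control) & tests$control == "max"]
  if (length(mx) == 0) {
    stop("no maximal-gene-flow control tests (P3 members as P2) present")
  }
  s_max <- mean(mx)
  if (s_max <= 0) {
    stop("maximal-control mean ABBA-BABA excess is non-positive (",
         signif(s_max, 3), "); admixture fraction f undefined")
  }
  ind <- dplyr::summarise(
    dplyr::group_by(tests, .data$p2_group, p2 = .data$p2),
    f_pct = 100 * mean(.data$s) / s_max, .groups = "drop"
  )
  taxa <- dplyr::summarise(dplyr::group_by(ind, .data$p2_group),
                           f_pct = mean(.data$f_pct), .groups = "drop")
  list(individuals = ind, taxa = taxa, s_max = s_max)
}

#' Reference-sample bias diagnostics
#'
#' The choice of individual representing P1, P3 or the outgroup can shift D
#' systematically (e.g. when a reference sample is itself introgressed).
#' For each role, this computes every reference individual's mean D over
#' the tests it participated in, its deviation from the grand mean D, a
#' one-way test of an individual effect (ANOVA by default, Kruskal-Wallis
#' as alternative), and flags outlier individuals whose absolute deviation
#' exceeds `threshold`.
#'
#' @param tests Per-test tibble from [run_individual_dstat()] (typically
#'   pre-filtered to the tests of interest, e.g. non-control tests).
#' @param threshold Absolute-deviation flag threshold (default 0.1; typical
#'   benign reference samples deviate by under ~0.09 while problematic ones
#'   reach 0.18-0.29 on real RAD data).
#' @param method `"anova"` or `"kruskal"`.
#' @return A `bias_analysis` list: `effects` (role, individual, n_tests,
#'   mean_d, deviation, outlier), `role_tests` (role, statistic, p_value,
#'   method) and `grand_mean`. Roles with a single individual are skipped
#'   with a warning. Within a role, deviations weighted by test counts sum
#'   to zero.
#' @export
reference_bias_analysis <- function(tests, threshold = 0.1,
                                    method = c("anova", "kruskal")) {
  method <- match.arg(method)
  ok <- !is.nan(tests$d)
  tests <- tests[ok, ]
  grand <- mean(tests$d)
  roles <- c(p1 = "p1", p3 = "p3", outgroup = "outgroup")
  eff <- list(); rt <- list()
  for (role in roles) {
    ids <- tests[[role]]
    if (length(unique(ids)) < 2) {
      warning("role ", role, " has a single individual; skipped")
      next
    }
    e <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(id = ids, d = tests$d), .data$id),
      n_tests = dplyr::n(), mean_d = mean(.data$d), .groups = "drop"
    )
    e <- dplyr::mutate(e, role = role, deviation = .data$mean_d - grand,
                       outlier = abs(.data$deviation) > threshold)
    eff[[role]] <- e
    pv <- if (method == "anova") {
      av <- stats::aov(tests$d ~ factor(ids))
      s <- summary(av)[[1]]
      tibble::tibble(role = role, statistic = s[["F value"]][1],
                     p_value = s[["Pr(>F)"]][1], method = "anova")
    } else {
      kt <- stats::kruskal.test(tests$d, factor(ids))
      tibble::tibble(role = role, statistic = unname(kt$statistic),
                     p_value = kt$p.value, method = "kruskal")
    }
    rt[[role]] <- pv
  }
  structure(
    list(effects = dplyr::bind_rows(eff)[
           , c("role", "id", "n_tests", "mean_d", "deviation", "outlier")],
         role_tests = dplyr::bind_rows(rt), grand_mean = grand),
    class = "bias_analysis"
  )
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("# Individual-based ABBA/BABA tests: %d tests, %d loci\n",
              nrow(x$tests), x$n_loci))
  print(x$taxa)
  invisible(x)
}

#' @export
tidy.dstat_result <- function(x, level = c("individuals", "tests", "taxa"),
                              ...) {
  level <- match.arg(level)
  x[[level]]
}

#' @export
glance.dstat_result <- function(x, ...) {
  focal <- x$taxa[is.na(x$taxa$control), ]
  tibble::tibble(
    n_tests = nrow(x$tests),
    n_loci = x$n_loci,
    n_excluded = sum(is.nan(x$tests$d)),
    s_max = x$s_max,
    mean_d = mean(focal$mean_d),
    mean_f_pct = mean(focal$f_pct)
  )
}

#' @export
autoplot.dstat_result <- function(object, ...) {
  ind <- object$individuals
  lab <- ifelse(is.na(ind$control), ind$p2_group,
                paste0(ind$p2_group, " (", ind$control, " control)"))
  df <- dplyr::mutate(ind, taxon = lab)
  sumdf <- dplyr::summarise(
    dplyr::group_by(df, .data$taxon),
    d = mean(.data$mean_d),
    lo = .data$d - 1.96 * stats::sd(.data$mean_d) / sqrt(dplyr::n()),
    hi = .data$d + 1.96 * stats::sd(.data$mean_d) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(sumdf, ggplot2::aes(x = .data$taxon, y = .data$d)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(x = .data$taxon, y = .data$mean_d),
                        alpha = 0.4, size = 1,
                        position = ggplot2::position_jitter(width = 0.08)) +
    ggplot2::labs(x = NULL, y = "Patterson's D (taxon mean ± 95% CI)") +
    ggplot2::theme_minimal()
}
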