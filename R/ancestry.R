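#' Find loci diagnostic between two parental groups
#'
#' Scans a complete biallelic genotype table for loci at which the two
#' parental groups are each monomorphic, for different alleles — the panel
#' used to place putative hybrids in the (q, Q12) triangle. "Fixed" means
#' fixed in the sample; an optional minor-allele-frequency relaxation is
#' available but defaults to strict fixation.
#'
#' @param gm A complete biallelic genotype table.
#' @param pm Population map.
#' @param parentA,parentB Group labels of the two parental taxa.
#' @param max_minor_freq Maximum within-parent frequency of the "wrong"
#'   allele still accepted as fixed (default 0 = strict).
#' @return A tibble of class `diagnostic_panel` with columns `locus`,
#'   `allele_a` (the allele fixed in parent A) and `allele_b`. Warns (not
#'   errors) when the panel is empty.
#' @examples
#' sim <- simulate_mosaic_hybrids(scenario_params(
#'   n_loci = 200, f = 0.25, mode = "mosaic", seed = 1))
#' panel <- find_diagnostic_loci(sim$genotypes, sim$popmap, "P1", "P3")
#' nrow(panel)
#' @export
find_diagnostic_loci <- function(gm, pm, parentA, parentB,
                                 max_minor_freq = 0) {
  pm <- validate_popmap(gm, pm)
  rec <- recode_biallelic(gm)
  dos <- rec$hapA + rec$hapB
  inds <- individual_ids(gm)
  ia <- inds %in% group_members(pm, parentA)
  ib <- inds %in% group_members(pm, parentB)
  pa <- rowSums(dos[, ia, drop = FALSE]) / (2 * sum(ia))
  pb <- rowSums(dos[, ib, drop = FALSE]) / (2 * sum(ib))
  fixed_diff <- (pa <= max_minor_freq & pb >= 1 - max_minor_freq) |
    (pa >= 1 - max_minor_freq & pb <= max_minor_freq)
  al <- rec$alleles[fixed_diff, , drop = FALSE]
  a_is_1 <- pa[fixed_diff] >= 0.5
  out <- tibble::tibble(
    locus = al$locus,
    allele_a = unname(ifelse(a_is_1, al$allele1, al$allele0)),
    allele_b = unname(ifelse(a_is_1, al$allele0, al$allele1))
  )
  if (nrow(out) == 0) warning("diagnostic panel is empty (0 loci)")
  structure(out, parentA = parentA, parentB = parentB,
            class = c("diagnostic_panel", class(tibble::tibble())))
}

#' Hybrid index q and inter-source heterozygosity Q12
#'
#' For each individual, over the L panel loci: `q` is the proportion of its
#' 2L gene copies that are the parent-B-type allele, and `Q12` the
#' proportion of panel loci at which it is heterozygous A-type/B-type.
#' Individuals from the parental groups themselves may be profiled; they
#' land near q = 0 or q = 1.
#'
#' @param gm A complete biallelic genotype table.
#' @param panel A `diagnostic_panel` from [find_diagnostic_loci()].
#' @param individuals Individuals to profile (default: all in `gm`).
#' @return A tibble with columns `individual`, `q`, `q12`, `n_loci`.
#' @export
ancestry_profile <- function(gm, panel, individuals = NULL) {
  if (nrow(panel) == 0) stop("diagnostic panel is empty")
  if (is.null(individuals)) individuals <- individual_ids(gm)
  unknown <- setdiff(individuals, individual_ids(gm))
  if (length(unknown) > 0) stop("unknown individual: ", unknown[1])
  mats <- geno_matrices(gm)
  li <- match(panel$locus, locus_ids(gm))
  if (anyNA(li)) stop("panel locus not present in matrix")
  ii <- match(individuals, individual_ids(gm))
  a1 <- mats$a1[li, ii, drop = FALSE]
  a2 <- mats$a2[li, ii, drop = FALSE]
  if (anyNA(a1) || anyNA(a2)) {
    stop("missing call at panel locus; apply filter_complete_biallelic() first")
  }
  bmat <- matrix(panel$allele_b, nrow(a1), ncol(a1))
  nb <- (a1 == bmat) + (a2 == bmat)
  L <- nrow(panel)
  tibble::tibble(
    individual = individuals,
    q = unname(colSums(nb)) / (2 * L),
    q12 = unname(colSums(nb == 1L)) / L,
    n_loci = L
  )
}

#' Triangle bounds on inter-source heterozygosity
#'
#' Given a hybrid index q, the maximum attainable Q12 is `2 * min(q, 1 - q)`
#' (attained when one parent of every individual is a pure parental; the
#' "backcross line"), and the Hardy-Weinberg expectation under random mating
#' within the hybrid population is `2 q (1 - q)`. Profiles falling well
#' below both lines indicate old, stabilized admixture rather than ongoing
#' hybridization.
#'
#' @param q Numeric vector of hybrid indices in `[0, 1]`.
#' @return A tibble with columns `q`, `q12_max`, `q12_hwe`.
#' @examples
#' q12_bounds(c(0, 0.155, 0.5))
#' @export
q12_bounds <- function(q) {
  if (any(q < 0 | q > 1 | is.na(q))) stop("q must lie in [0, 1]")
  tibble::tibble(q = q, q12_max = 2 * pmin(q, 1 - q), q12_hwe = 2 * q * (1 - q))
}

#' Hybrid-triangle plot of ancestry profiles
#'
#' Scatter of per-individual (q, Q12) with the maximum (solid) and
#' Hardy-Weinberg (dashed) bound curves.
#'
#' @param profiles A tibble from [ancestry_profile()]; an optional `group`
#'   column colours the points.
#' @return A ggplot object.
#' @export
plot_triangle <- function(profiles) {
  bounds <- q12_bounds(seq(0, 1, length.out = 101))
  p <- ggplot2::ggplot(profiles, ggplot2::aes(x = .data$q, y = .data$q12)) +
    ggplot2::geom_line(data = bounds,
                       ggplot2::aes(x = .data$q, y = .data$q12_max),
                       linewidth = 0.4) +
    ggplot2::geom_line(data = bounds,
                       ggplot2::aes(x = .data$q, y = .data$q12_hwe),
                       linetype = "dashed", linewidth = 0.4)
  if ("group" %in% names(profiles)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = "hybrid index q",
                    y = expression(Q[12] ~ "(inter-source heterozygosity)")) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
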