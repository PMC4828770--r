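#' Simulation scenario parameters
#'
#' Parameters for the four-taxon SNP simulators. The species tree is
#' (((P1, H), P3), O) with H the putative hybrid lineage; each branch
#' applies Balding-Nichols beta drift with its own intensity `c` in (0, 1)
#' (the expected single-branch Fst). An admixture pulse moves a fraction
#' `f` of the hybrid gene pool from P3, `n_generations` before sampling.
#' Defaults mirror a typical ddRAD study design: a complete matrix of 977
#' polymorphic biallelic loci scored for 8 P1, 12 hybrid, 12 P3 and 3
#' outgroup individuals, with drift intensities chosen so that the
#' simulated P1-clade vs P3 Fst lands around 0.6-0.75, the scale observed
#' between strongly diverged congeneric vipers.
#'
#' @param n_loci Number of polymorphic, fully genotyped loci to emit.
#' @param n_p1,n_hybrid,n_p3,n_out Diploid sample sizes per taxon.
#' @param c_out,c_ingroup,c_p3,c_split,c_p1,c_h Branch drift intensities:
#'   root to outgroup, root to ingroup ancestor, ingroup ancestor to P3,
#'   ingroup ancestor to the (P1, H) ancestor, and that ancestor to P1 and
#'   to the H lineage.
#' @param f Admixture fraction from P3 into the hybrid group, in `[0, 1]`.
#' @param n_generations Generations since the pulse: binomial drift
#'   generations in frequency mode, random-mating rounds in mosaic mode.
#' @param mode `"frequency"` or `"mosaic"`.
#' @param seed Integer RNG seed (the output is byte-identical given it).
#' @param ne Hybrid effective population size for post-pulse drift
#'   (frequency mode).
#' @param n_virtual Virtual hybrid population size for mosaic mating
#'   rounds; large enough that inbreeding decay of heterozygosity over a
#'   few generations is negligible.
#' @param beta_shape Shape of the symmetric beta distribution of ancestral
#'   derived-allele frequencies (0.5 = Jeffreys, U-shaped).
#' @return A `scenario_params` list.
#' @export
scenario_params <- function(n_loci = 977, n_p1 = 8, n_hybrid = 12,
                            n_p3 = 12, n_out = 3,
                            c_out = 0.6, c_ingroup = 0.15, c_p3 = 0.75,
                            c_split = 0.35, c_p1 = 0.25, c_h = 0.25,
                            f = 0, n_generations = 0,
                            mode = c("frequency", "mosaic"), seed = 1,
                            ne = 100, n_virtual = 400, beta_shape = 0.5) {
  mode <- match.arg(mode)
  cs <- c(c_out, c_ingroup, c_p3, c_split, c_p1, c_h)
  if (any(cs <= 0 | cs >= 1)) stop("drift parameters must lie in (0, 1)")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  sizes <- c(n_p1, n_hybrid, n_p3, n_out)
  if (any(sizes < 1)) stop("sample sizes must be >= 1")
  if (n_generations < 0) stop("n_generations must be >= 0")
  structure(list(n_loci = n_loci, n_p1 = n_p1, n_hybrid = n_hybrid,
                 n_p3 = n_p3, n_out = n_out, c_out = c_out,
                 c_ingroup = c_ingroup, c_p3 = c_p3, c_split = c_split,
                 c_p1 = c_p1, c_h = c_h, f = f,
                 n_generations = n_generations, mode = mode, seed = seed,
                 ne = ne, n_virtual = n_virtual, beta_shape = beta_shape),
            class = "scenario_params")
}

# Balding-Nichols drift: child frequency ~ Beta(p(1-c)/c, (1-p)(1-c)/c);
# fixed frequencies stay fixed
bn_drift <- function(p, c) {
  out <- p
  seg <- p > 0 & p < 1
  k <- (1 - c) / c
  out[seg] <- stats::rbeta(sum(seg), p[seg] * k, (1 - p[seg]) * k)
  out
}

# per-locus lineage frequencies for a batch of loci
sim_lineage_freqs <- function(L, params, f) {
  p_root <- stats::rbeta(L, params$beta_shape, params$beta_shape)
  p_out <- bn_drift(p_root, params$c_out)
  p_ing <- bn_drift(p_root, params$c_ingroup)
  p_p3 <- bn_drift(p_ing, params$c_p3)
  p_12 <- bn_drift(p_ing, params$c_split)
  p_p1 <- bn_drift(p_12, params$c_p1)
  p_h0 <- bn_drift(p_12, params$c_h)
  p_hyb <- (1 - f) * p_h0 + f * p_p3
  if (params$n_generations > 0) {
    for (g in seq_len(params$n_generations)) {
      p_hyb <- stats::rbinom(L, 2 * params$ne, p_hyb) / (2 * params$ne)
    }
  }
  tibble::tibble(p_root = p_root, p_out = p_out, p_p3 = p_p3,
                 p_p1 = p_p1, p_h0 = p_h0, p_hybrid = p_hyb)
}

# draw a pair of 0/1 haplotype matrices (L x n) at frequency p (length L)
sample_haps <- function(p, n) {
  L <- length(p)
  list(A = matrix(stats::rbinom(L * n, 1L, rep(p, n)), L, n),
       B = matrix(stats::rbinom(L * n, 1L, rep(p, n)), L, n))
}

sim_individual_ids <- function(params) {
  list(P1 = sprintf("P1_%02d", seq_len(params$n_p1)),
       H = sprintf("H_%02d", seq_len(params$n_hybrid)),
       P3 = sprintf("P3_%02d", seq_len(params$n_p3)),
       O = sprintf("O_%02d", seq_len(params$n_out)))
}

sim_popmap <- function(ids) {
  tibble::tibble(
    individual = unlist(ids, use.names = FALSE),
    group = rep(names(ids), lengths(ids))
  )
}

# assemble a geno_tbl from per-group hap matrices and allele labels
assemble_geno <- function(locus_ids, ids, haps, anc, der) {
  inds <- unlist(ids, use.names = FALSE)
  A <- do.call(cbind, lapply(haps, `[[`, "A"))
  B <- do.call(cbind, lapply(haps, `[[`, "B"))
  lab <- function(h) ifelse(h == 1L, der[row(h)], anc[row(h)])
  n_ind <- length(inds)
  as_geno_tbl(tibble::tibble(
    locus = rep(locus_ids, times = n_ind),
    individual = rep(inds, each = length(locus_ids)),
    a1 = as.vector(lab(A)), a2 = as.vector(lab(B))
  ), locus_ids = locus_ids, individual_ids = inds)
}

draw_allele_labels <- function(L) {
  nuc <- c("A", "C", "G", "T")
  anc <- sample(nuc, L, replace = TRUE)
  shift <- sample(1:3, L, replace = TRUE)
  der <- nuc[(match(anc, nuc) - 1L + shift) %% 4L + 1L]
  list(anc = anc, der = der)
}

#' Simulate a four-taxon SNP dataset by frequency drift
#'
#' Ancestral derived-allele frequencies are drawn from a U-shaped beta
#' distribution and evolve down each branch of (((P1, H), P3), O) by
#' Balding-Nichols drift, which preserves shared ancestral polymorphism
#' (incomplete lineage sorting) across taxa. The hybrid population's
#' frequency is the convex combination `(1 - f) p_sister + f p_P3`,
#' followed by `n_generations` of binomial drift at size `2 ne`. Diploid
#' genotypes are drawn binomially; loci monomorphic across the sampled
#' matrix are dropped and redrawn so the output is exactly `n_loci`
#' polymorphic, fully genotyped biallelic loci — it passes
#' [filter_complete_biallelic()] unchanged.
#'
#' @param params A [scenario_params()] with `mode = "frequency"`.
#' @return A `sim_scenario` list: `genotypes` (`geno_tbl`), `popmap`
#'   (groups `P1`, `H`, `P3`, `O`), `truth` (true `f`, per-locus ancestral
#'   allele, per-locus lineage frequencies) and `params`.
#' @export
simulate_frequency_scenario <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  if (params$mode != "frequency") stop('params$mode must be "frequency"')
  ids <- sim_individual_ids(params)
  n_per <- c(params$n_p1, params$n_hybrid, params$n_p3, params$n_out)
  with_seed(params$seed, {
    kept_haps <- NULL; kept_freq <- NULL; kept_anc <- NULL; kept_der <- NULL
    n_have <- 0L
    while (n_have < params$n_loci) {
      L <- max(64L, ceiling((params$n_loci - n_have) * 1.4))
      fr <- sim_lineage_freqs(L, params, params$f)
      hp <- list(P1 = sample_haps(fr$p_p1, n_per[1]),
                 H = sample_haps(fr$p_hybrid, n_per[2]),
                 P3 = sample_haps(fr$p_p3, n_per[3]),
                 O = sample_haps(fr$p_out, n_per[4]))
      tot <- Reduce(`+`, lapply(hp, function(h) rowSums(h$A) + rowSums(h$B)))
      poly <- tot > 0 & tot < 2 * sum(n_per)
      lab <- draw_allele_labels(L)
      keep <- which(poly)
      if (length(keep) > 0) {
        sel_haps <- lapply(hp, function(h) {
          list(A = h$A[keep, , drop = FALSE], B = h$B[keep, , drop = FALSE])
        })
        kept_haps <- if (is.null(kept_haps)) sel_haps else {
          purrr::map2(kept_haps, sel_haps, function(a, b) {
            list(A = rbind(a$A, b$A), B = rbind(a$B, b$B))
          })
        }
        kept_freq <- dplyr::bind_rows(kept_freq, fr[keep, ])
        kept_anc <- c(kept_anc, lab$anc[keep])
        kept_der <- c(kept_der, lab$der[keep])
        n_have <- n_have + length(keep)
      }
    }
    take <- seq_len(params$n_loci)
    haps <- lapply(kept_haps, function(h) {
      list(A = h$A[take, , drop = FALSE], B = h$B[take, , drop = FALSE])
    })
    lids <- sprintf("loc%05d", take)
    gm <- assemble_geno(lids, ids, haps, kept_anc[take], kept_der[take])
    truth <- list(
      f = params$f,
      ancestral = tibble::tibble(locus = lids,
                                 ancestral_allele = kept_anc[take],
                                 derived_allele = kept_der[take]),
      lineage_freqs = dplyr::bind_cols(tibble::tibble(locus = lids),
                                       kept_freq[take, ]),
      sources = NULL
    )
    structure(list(genotypes = gm, popmap = sim_popmap(ids),
                   truth = truth, params = params),
              class = "sim_scenario")
  })
}

#' Simulate mosaic hybrid individuals with known ancestry
#'
#' Parental (P1, P3) and outgroup pools are simulated as in
#' [simulate_frequency_scenario()] with no gene flow; hybrid genomes are
#' then built as locus-level mosaics of the sampled parental haplotypes,
#' with every copy's source recorded in the truth table. At generation 0
#' each hybrid haplotype has a single source for all loci, arranged to
#' maximise inter-source heterozygosity: for `f <= 0.5` an individual
#' carries one P3-derived haplotype with probability `2f` (so `f = 0.5`
#' gives exact F1s, and expected Q12 sits on the backcross line
#' `2 min(q, 1 - q)`). Each of `n_generations` rounds of random mating in a
#' virtual population of `n_virtual` individuals then recombines ancestry
#' freely across the unlinked loci, so Q12 decays toward the
#' Hardy-Weinberg value `2 f (1 - f)`. Output hybrids are sampled from the
#' final virtual generation.
#'
#' @param params A [scenario_params()] with `mode = "mosaic"`.
#' @return A `sim_scenario` as in [simulate_frequency_scenario()], whose
#'   `truth$sources` records the source pool (`"P1"` or `"P3"`) of every
#'   (hybrid, haplotype, locus) copy.
#' @export
simulate_mosaic_hybrids <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  if (params$mode != "mosaic") stop('params$mode must be "mosaic"')
  ids <- sim_individual_ids(params)
  n_per <- c(params$n_p1, params$n_hybrid, params$n_p3, params$n_out)
  nv <- params$n_virtual
  with_seed(params$seed, {
    kept <- NULL
    n_have <- 0L
    # whole-haplotype source labels of the founding virtual generation
    k_p3 <- if (params$f <= 0.5) {
      stats::rbinom(nv, 1L, 2 * params$f)
    } else {
      1L + stats::rbinom(nv, 1L, 2 * params$f - 1)
    }
    srcA0 <- k_p3 >= 1L   # per-individual constant over loci at g = 0
    srcB0 <- k_p3 == 2L
    while (n_have < params$n_loci) {
      L <- max(64L, ceiling((params$n_loci - n_have) * 1.4))
      fr <- sim_lineage_freqs(L, params, 0)
      hp <- list(P1 = sample_haps(fr$p_p1, n_per[1]),
                 P3 = sample_haps(fr$p_p3, n_per[3]),
                 O = sample_haps(fr$p_out, n_per[4]))
      # virtual hybrid ancestry labels (TRUE = P3 source), L x nv per hap
      SA <- matrix(srcA0, L, nv, byrow = TRUE)
      SB <- matrix(srcB0, L, nv, byrow = TRUE)
      if (params$n_generations > 0) {
        for (g in seq_len(params$n_generations)) {
          par1 <- sample.int(nv, nv, replace = TRUE)
          par2 <- ((par1 - 1L + sample.int(nv - 1L, nv, replace = TRUE))
                   %% nv) + 1L  # a different parent
          pickA <- matrix(stats::runif(L * nv) < 0.5, L, nv)
          pickB <- matrix(stats::runif(L * nv) < 0.5, L, nv)
          SA_new <- ifelse(pickA, SA[, par1, drop = FALSE],
                           SB[, par1, drop = FALSE])
          SB_new <- ifelse(pickB, SA[, par2, drop = FALSE],
                           SB[, par2, drop = FALSE])
          SA <- SA_new; SB <- SB_new
        }
      }
      pick_out <- sample.int(nv, n_per[2])
      SA <- SA[, pick_out, drop = FALSE]
      SB <- SB[, pick_out, drop = FALSE]
      # copy alleles per locus from a random haplotype of the source pool
      pool <- list(P1 = cbind(hp$P1$A, hp$P1$B), P3 = cbind(hp$P3$A, hp$P3$B))
      copy_from <- function(S) {
        n_h <- ncol(S)
        out <- matrix(0L, L, n_h)
        for (pl in c("P1", "P3")) {
          sel <- if (pl == "P3") S else !S
          nc <- ncol(pool[[pl]])
          draw <- matrix(sample.int(nc, L * n_h, replace = TRUE), L, n_h)
          idx <- which(sel)
          out[idx] <- pool[[pl]][cbind(((idx - 1L) %% L) + 1L,
                                       draw[idx])]
        }
        out
      }
      HA <- copy_from(SA)
      HB <- copy_from(SB)
      hp_all <- list(P1 = hp$P1, H = list(A = HA, B = HB),
                     P3 = hp$P3, O = hp$O)
      tot <- Reduce(`+`,
                    lapply(hp_all, function(h) rowSums(h$A) + rowSums(h$B)))
      poly <- tot > 0 & tot < 2 * sum(n_per)
      lab <- draw_allele_labels(L)
      keep <- which(poly)
      if (length(keep) > 0) {
        chunk <- list(
          haps = lapply(hp_all, function(h) {
            list(A = h$A[keep, , drop = FALSE],
                 B = h$B[keep, , drop = FALSE])
          }),
          freq = fr[keep, ],
          anc = lab$anc[keep], der = lab$der[keep],
          srcA = SA[keep, , drop = FALSE], srcB = SB[keep, , drop = FALSE]
        )
        kept <- if (is.null(kept)) chunk else list(
          haps = purrr::map2(kept$haps, chunk$haps, function(a, b) {
            list(A = rbind(a$A, b$A), B = rbind(a$B, b$B))
          }),
          freq = dplyr::bind_rows(kept$freq, chunk$freq),
          anc = c(kept$anc, chunk$anc), der = c(kept$der, chunk$der),
          srcA = rbind(kept$srcA, chunk$srcA),
          srcB = rbind(kept$srcB, chunk$srcB)
        )
        n_have <- n_have + length(keep)
      }
    }
    take <- seq_len(params$n_loci)
    haps <- lapply(kept$haps, function(h) {
      list(A = h$A[take, , drop = FALSE], B = h$B[take, , drop = FALSE])
    })
    lids <- sprintf("loc%05d", take)
    gm <- assemble_geno(lids, ids, haps, kept$anc[take], kept$der[take])
    srcA <- kept$srcA[take, , drop = FALSE]
    srcB <- kept$srcB[take, , drop = FALSE]
    sources <- tibble::tibble(
      individual = rep(rep(ids$H, each = length(lids)), 2),
      haplotype = rep(c("A", "B"), each = length(lids) * length(ids$H)),
      locus = rep(lids, times = 2 * length(ids$H)),
      source = ifelse(c(as.vector(srcA), as.vector(srcB)), "P3", "P1")
    )
    truth <- list(
      f = params$f,
      ancestral = tibble::tibble(locus = lids,
                                 ancestral_allele = kept$anc[take],
                                 derived_allele = kept$der[take]),
      lineage_freqs = dplyr::bind_cols(tibble::tibble(locus = lids),
                                       kept$freq[take, ]),
      sources = sources
    )
    structure(list(genotypes = gm, popmap = sim_popmap(ids),
                   truth = truth, params = params),
              class = "sim_scenario")
  })
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "# Simulated %s-mode scenario: %d loci, f = %g, %d generations, seed %d\n",
    x$params$mode, x$params$n_loci, x$params$f, x$params$n_generations,
    x$params$seed))
  print(x$genotypes)
  invisible(x)
}
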