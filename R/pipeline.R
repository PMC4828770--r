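#' Simulate a dataset and write it to disk
#'
#' Runs the configured simulator and writes the genotype matrix (TSV and
#' VCF), population map, truth tables and echoed parameters into
#' `out_dir`, in the same formats [read_genotypes()] / [read_popmap()]
#' read. Re-running with the same parameters reproduces the files
#' byte-for-byte.
#'
#' @param params A [scenario_params()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
pipeline_simulate <- function(params, out_dir) {
  stopifnot(inherits(params, "scenario_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- if (params$mode == "frequency") {
    simulate_frequency_scenario(params)
  } else {
    simulate_mosaic_hybrids(params)
  }
  paths <- c(
    genotypes_tsv = file.path(out_dir, "genotypes.tsv"),
    genotypes_vcf = file.path(out_dir, "genotypes.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    truth_loci = file.path(out_dir, "truth_loci.tsv"),
    params = file.path(out_dir, "params.yaml")
  )
  write_genotypes(sim$genotypes, paths[["genotypes_tsv"]], "tsv")
  write_genotypes(sim$genotypes, paths[["genotypes_vcf"]], "vcf")
  write_popmap(sim$popmap, paths[["popmap"]])
  loci <- dplyr::left_join(sim$truth$ancestral, sim$truth$lineage_freqs,
                           by = "locus")
  readr::write_tsv(loci, paths[["truth_loci"]], progress = FALSE)
  if (!is.null(sim$truth$sources)) {
    paths <- c(paths, truth_sources = file.path(out_dir, "truth_sources.tsv"))
    readr::write_tsv(sim$truth$sources, paths[["truth_sources"]],
                     progress = FALSE)
  }
  yaml::write_yaml(c(unclass(params)), paths[["params"]])
  message(sprintf("[simulate] wrote %d loci x %d individuals to %s",
                  params$n_loci, nrow(sim$popmap), out_dir))
  invisible(paths)
}

#' End-to-end introgression analysis
#'
#' Runs the full pipeline on a genotype matrix + population map: complete
#' biallelic filter, per-group diversity, pairwise Fst with permutation
#' test, diagnostic-locus q/Q12 profiles with triangle bounds, exhaustive
#' individual-based ABBA/BABA tests with controls, admixture proportion f,
#' reference-sample bias diagnostics, and population-frequency D with
#' binomial bootstrap for every P2 candidate group. Each table is written
#' as a TSV in `out_dir` (when given) together with a JSON metadata
#' sidecar recording the configuration, the derived stage seeds and
#' excluded-test counts; one log line is emitted per stage. All stage
#' seeds derive from the single master `seed` by fixed offsets (+1 Fst
#' permutations, +2 bootstrap), so partial re-runs are reproducible. No
#' table cell is recomputed outside the module that owns it.
#'
#' @param gm A genotype table (will be filtered here).
#' @param pm Population map.
#' @param cfg A [quartet_config()].
#' @param out_dir Optional output directory for the report bundle.
#' @param n_perm Fst permutations.
#' @param n_reps Bootstrap replicates for the population D.
#' @param rarefaction_n Rarefaction depth for allelic richness (default
#'   `2 * min(group size)`).
#' @param seed Master seed.
#' @return An `introgression_report` list with elements `diversity`,
#'   `fst`, `panel`, `ancestry`, `dstat` (a `dstat_result`), `bias`,
#'   `population_d` (list of `pop_dstat` by P2 group) and `meta`.
#' @export
pipeline_analyze <- function(gm, pm, cfg, out_dir = NULL, n_perm = 1000,
                             n_reps = 100, rarefaction_n = NULL, seed = 1) {
  stopifnot(inherits(cfg, "quartet_config"))
  t0 <- Sys.time()
  stage <- function(name, n_in, n_out) {
    message(sprintf("[%s] %s -> %s (%.1fs)", name, n_in, n_out,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  pm <- validate_popmap(gm, pm)

  gmf <- filter_complete_biallelic(gm)
  stage("filter", paste0(length(locus_ids(gm)), " loci"),
        paste0(length(locus_ids(gmf)), " complete biallelic loci"))

  div <- diversity_table(gmf, pm, rarefaction_n)
  stage("diversity", "groups", nrow(div))

  fst <- pairwise_fst(gmf, pm, n_perm = n_perm, seed = seed + 1L)
  stage("fst", "pairs", nrow(fst))

  panel <- find_diagnostic_loci(gmf, pm, cfg$p1, cfg$p3)
  anc <- if (nrow(panel) > 0) {
    dplyr::left_join(ancestry_profile(gmf, panel), pm, by = "individual")
  } else {
    tibble::tibble(individual = character(), q = numeric(),
                   q12 = numeric(), n_loci = integer(), group = character())
  }
  stage("ancestry", paste0(nrow(panel), " diagnostic loci"), nrow(anc))

  dst <- run_individual_dstat(gmf, pm, cfg)
  stage("dstat-individual", paste0(nrow(dst$tests), " tests"),
        paste0(sum(is.nan(dst$tests$d)), " excluded (no informative sites)"))

  focal <- dst$tests[is.na(dst$tests$control), ]
  bias <- reference_bias_analysis(focal)
  stage("bias", "roles", nrow(bias$role_tests))

  popd <- lapply(cfg$p2, function(g) {
    bootstrap_population_d(population_dstat(gmf, pm, cfg, g),
                           n_reps = n_reps, seed = seed + 2L)
  })
  names(popd) <- cfg$p2
  stage("dstat-population", paste(cfg$p2, collapse = ","), length(popd))

  meta <- list(
    package_version = as.character(utils::packageVersion("introgressr")),
    n_loci_input = length(locus_ids(gm)),
    n_loci_used = length(locus_ids(gmf)),
    groups = as.list(table(pm$group)),
    roles = list(p1 = cfg$p1, p2 = cfg$p2, p3 = cfg$p3,
                 outgroup = cfg$outgroup),
    allele_scheme = cfg$allele_scheme,
    n_panel_loci = nrow(panel),
    n_tests = nrow(dst$tests),
    n_tests_excluded = sum(is.nan(dst$tests$d)),
    s_max = dst$s_max,
    seeds = list(master = seed, fst = seed + 1L, bootstrap = seed + 2L),
    n_perm = n_perm, n_reps = n_reps
  )
  report <- structure(
    list(diversity = div, fst = fst, panel = panel, ancestry = anc,
         dstat = dst, bias = bias, population_d = popd, meta = meta),
    class = "introgression_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# TSV/JSON report bundle; every cell comes straight from a module result
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  w(report$diversity, "diversity.tsv")
  w(tidy(report$fst), "fst.tsv")
  w(tibble::as_tibble(report$panel), "diagnostic_panel.tsv")
  w(report$ancestry, "ancestry.tsv")
  w(q12_bounds(seq(0, 1, length.out = 101)), "triangle_bounds.tsv")
  w(report$dstat$tests, "dstat_tests.tsv")
  w(report$dstat$individuals, "dstat_individuals.tsv")
  w(report$dstat$taxa, "dstat_taxa.tsv")
  w(report$bias$effects, "bias_effects.tsv")
  w(report$bias$role_tests, "bias_tests.tsv")
  popd <- dplyr::bind_rows(lapply(names(report$population_d), function(g) {
    dplyr::bind_cols(tibble::tibble(p2_group = g),
                     glance(report$population_d[[g]]))
  }))
  w(popd, "population_d.tsv")
  jsonlite::write_json(report$meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.introgression_report <- function(x, ...) {
  cat("# Introgression analysis report\n")
  cat(sprintf("  loci used: %d of %d; diagnostic panel: %d loci\n",
              x$meta$n_loci_used, x$meta$n_loci_input, x$meta$n_panel_loci))
  print(x$dstat$taxa)
  invisible(x)
}
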