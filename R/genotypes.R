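#' Genotype tables
#'
#' `introgressr` stores diploid SNP genotypes in a long tibble — the
#' "genotype table" — with one row per (locus, individual) call and columns
#' `locus`, `individual`, `a1`, `a2`. The two allele columns hold single
#' allele codes (nucleotides or arbitrary symbols); a missing call has `NA`
#' in both. Genotypes are unphased: `a1`/`a2` is the storage order of the
#' input file (VCF GT order, TSV column order), which is arbitrary but fixed,
#' making downstream two-haplotype analyses deterministic for a given file.
#'
#' @param x A data frame with columns `locus`, `individual`, `a1`, `a2`.
#' @param locus_ids,individual_ids Optional character vectors fixing the
#'   locus/individual ordering; default is order of first appearance.
#' @return A tibble of class `geno_tbl` covering the full locus x individual
#'   grid (absent combinations become missing calls).
#' @examples
#' gt <- as_geno_tbl(data.frame(
#'   locus = c("L1", "L1", "L2", "L2"),
#'   individual = c("i1", "i2", "i1", "i2"),
#'   a1 = c("A", "A", "C", "C"),
#'   a2 = c("G", "A", "C", "T")))
#' locus_stats(gt)
#' @export
as_geno_tbl <- function(x, locus_ids = NULL, individual_ids = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("locus", "individual", "a1", "a2")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  x <- tibble::as_tibble(x)[need]
  x$locus <- as.character(x$locus)
  x$individual <- as.character(x$individual)
  x$a1 <- as.character(x$a1)
  x$a2 <- as.character(x$a2)
  # a half-missing diploid call is treated as missing outright
  half <- xor(is.na(x$a1), is.na(x$a2))
  if (any(half)) {
    x$a1[half] <- NA_character_
    x$a2[half] <- NA_character_
  }
  if (anyDuplicated(x[c("locus", "individual")]) > 0) {
    d <- x[duplicated(x[c("locus", "individual")]), , drop = FALSE]
    stop("duplicate (locus, individual) call(s), e.g. ",
         d$locus[1], " / ", d$individual[1])
  }
  if (is.null(locus_ids)) locus_ids <- unique(x$locus)
  if (is.null(individual_ids)) individual_ids <- unique(x$individual)
  if (anyDuplicated(individual_ids) > 0) stop("duplicate individual id")
  if (anyDuplicated(locus_ids) > 0) stop("duplicate locus id")
  x <- tidyr::complete(
    x,
    locus = factor(locus_ids, levels = locus_ids),
    individual = factor(individual_ids, levels = individual_ids)
  )
  x$locus <- as.character(x$locus)
  x$individual <- as.character(x$individual)
  x <- dplyr::arrange(
    x,
    match(.data$locus, locus_ids), match(.data$individual, individual_ids)
  )
  new_geno_tbl(x, locus_ids, individual_ids)
}

new_geno_tbl <- function(x, locus_ids, individual_ids) {
  structure(
    tibble::as_tibble(x),
    locus_ids = locus_ids,
    individual_ids = individual_ids,
    class = c("geno_tbl", class(tibble::tibble()))
  )
}

#' @export
print.geno_tbl <- function(x, ...) {
  cat(sprintf(
    "# Genotype table: %d loci x %d individuals (%d missing calls)\n",
    length(attr(x, "locus_ids")), length(attr(x, "individual_ids")),
    sum(is.na(x$a1))
  ))
  NextMethod()
}

#' @rdname as_geno_tbl
#' @export
locus_ids <- function(x) attr(x, "locus_ids")

#' @rdname as_geno_tbl
#' @export
individual_ids <- function(x) attr(x, "individual_ids")

#' Per-locus allele summaries
#'
#' @param gm A genotype table (see [as_geno_tbl()]).
#' @return A tibble with one row per locus: observed allele labels
#'   (list-column `alleles`), `n_alleles`, `n_missing` calls, and logical
#'   flags `biallelic` (exactly two observed alleles) and `complete`
#'   (no missing calls). Multi-allelic loci are flagged, never dropped here.
#' @export
locus_stats <- function(gm) {
  lids <- locus_ids(gm)
  long <- tidyr::pivot_longer(gm, c("a1", "a2"),
                              names_to = NULL, values_to = "allele")
  by_locus <- dplyr::summarise(
    dplyr::group_by(long, .data$locus),
    alleles = list(sort(unique(.data$allele[!is.na(.data$allele)]))),
    n_alleles = length(.data$alleles[[1]]),
    n_missing = sum(is.na(.data$allele)) / 2L,
    .groups = "drop"
  )
  by_locus <- by_locus[match(lids, by_locus$locus), ]
  dplyr::mutate(by_locus,
                biallelic = .data$n_alleles == 2L,
                complete = .data$n_missing == 0L)
}

#' Read a genotype matrix from VCF or TSV
#'
#' Two dialects are supported. The genotype TSV has a header line
#' `locus individual allele1 allele2` (tab-separated) with missing alleles
#' written `.`. VCF (v4.x) records are read through \pkg{vcfR}; the GT field
#' is required, allele indices are translated to REF/ALT codes, and
#' multi-allelic records are retained (they are flagged by [locus_stats()]
#' and removed by [filter_complete_biallelic()]). RAD data conventions:
#' CHROM carries the RAD locus id and POS the site offset; when every CHROM
#' value is unique the CHROM alone is used as the locus id, otherwise
#' `CHROM:POS`. No genomic arithmetic is performed and strand is never
#' complemented — RAD loci are anonymous.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A `geno_tbl` preserving the input ordering of loci and
#'   individuals, with missing calls kept as `NA`.
#' @seealso [write_genotypes()], [read_popmap()]
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("locus", "individual", "allele1", "allele2")
  if (!all(need %in% names(x))) {
    stop("genotype TSV must have header: ", paste(need, collapse = "\t"))
  }
  bad <- which(is.na(x$locus) | is.na(x$individual))
  if (length(bad) > 0) {
    stop("malformed genotype TSV record at data line ", bad[1])
  }
  x$allele1[x$allele1 == "."] <- NA_character_
  x$allele2[x$allele2 == "."] <- NA_character_
  as_geno_tbl(data.frame(locus = x$locus, individual = x$individual,
                         a1 = x$allele1, a2 = x$allele2))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- fix[, "POS"]
  ids <- if (anyDuplicated(chrom) == 0) chrom else paste0(chrom, ":", pos)
  if (anyDuplicated(ids) > 0) stop("duplicate locus id (CHROM:POS) in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  inds <- colnames(gt)
  if (anyDuplicated(inds) > 0) stop("duplicate individual id in VCF header")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  allele_list <- lapply(seq_along(ref), function(i) {
    c(ref[i], strsplit(ifelse(is.na(alt[i]), "", alt[i]), ",", fixed = TRUE)[[1]])
  })
  n_loc <- length(ids)
  n_ind <- length(inds)
  a1 <- matrix(NA_character_, n_loc, n_ind)
  a2 <- matrix(NA_character_, n_loc, n_ind)
  for (i in seq_len(n_loc)) {
    g <- gt[i, ]
    g[is.na(g)] <- "./."
    parts <- stringr::str_split_fixed(g, "[/|]", 2)
    if (any(parts[, 2] == "")) {
      stop("non-diploid GT in VCF record ", ids[i])
    }
    al <- allele_list[[i]]
    idx1 <- suppressWarnings(as.integer(parts[, 1])) + 1L
    idx2 <- suppressWarnings(as.integer(parts[, 2])) + 1L
    a1[i, ] <- al[idx1]
    a2[i, ] <- al[idx2]
  }
  as_geno_tbl(data.frame(
    locus = rep(ids, times = n_ind),
    individual = rep(inds, each = n_loc),
    a1 = as.vector(a1), a2 = as.vector(a2)
  ), locus_ids = ids, individual_ids = inds)
}

#' Write a genotype matrix to VCF or TSV
#'
#' The TSV writer round-trips exactly through [read_genotypes()]. The VCF
#' writer emits minimal v4.2 records (CHROM = locus id, POS = 1, REF/ALT =
#' observed alleles in sorted order) and round-trips for biallelic matrices
#' whose locus ids contain no `:`.
#'
#' @param gm A genotype table.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- dplyr::transmute(
      gm, .data$locus, .data$individual,
      allele1 = dplyr::coalesce(.data$a1, "."),
      allele2 = dplyr::coalesce(.data$a2, ".")
    )
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(path))
  }
  st <- locus_stats(gm)
  inds <- individual_ids(gm)
  lids <- locus_ids(gm)
  mats <- geno_matrices(gm)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=introgressr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t")
  )
  body <- vapply(seq_along(lids), function(i) {
    al <- st$alleles[[i]]
    if (length(al) == 0) al <- "N"
    ref <- al[1]
    alt <- if (length(al) > 1) paste(al[-1], collapse = ",") else "."
    code <- function(x) {
      ifelse(is.na(x), ".", as.character(match(x, al) - 1L))
    }
    gts <- paste(code(mats$a1[i, ]), code(mats$a2[i, ]), sep = "/")
    paste(c(lids[i], "1", ".", ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read / write a population map
#'
#' A population map assigns each individual to a taxon (group). File format:
#' tab-separated `individual group`, with header.
#'
#' @param path Path to the population-map TSV.
#' @return A tibble with columns `individual`, `group`.
#' @export
read_popmap <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("individual", "group") %in% names(x))) {
    stop("population map must have header: individual\tgroup")
  }
  if (anyDuplicated(x$individual) > 0) {
    stop("individual assigned to more than one group: ",
         x$individual[duplicated(x$individual)][1])
  }
  tibble::as_tibble(x[c("individual", "group")])
}

#' @rdname read_popmap
#' @param pm A population map tibble.
#' @export
write_popmap <- function(pm, path) {
  readr::write_tsv(pm[c("individual", "group")], path, progress = FALSE)
  invisible(path)
}

#' Check a population map against a genotype table
#'
#' Errors unless every individual in the matrix has exactly one group and
#' every group is non-empty.
#'
#' @param gm A genotype table.
#' @param pm A population map (`individual`, `group`).
#' @return `pm` (restricted to matrix individuals), invisibly.
#' @export
validate_popmap <- function(gm, pm) {
  inds <- individual_ids(gm)
  if (anyDuplicated(pm$individual) > 0) {
    stop("individual assigned to more than one group")
  }
  missing <- setdiff(inds, pm$individual)
  if (length(missing) > 0) {
    stop("individual(s) missing from population map: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(pm[pm$individual %in% inds, ])
}

group_members <- function(pm, group) {
  out <- pm$individual[pm$group %in% group]
  if (length(out) == 0) stop("empty group: ", paste(group, collapse = ", "))
  out
}

#' Keep complete, biallelic loci
#'
#' Restricts a genotype table to loci that carry exactly two observed
#' alleles and are genotyped in every individual — the same rule that
#' reduces a RADseq SNP set to the fully genotyped polymorphic core used by
#' all downstream analyses. Locus order is preserved and the operation is
#' idempotent. Missing data are never imputed.
#'
#' @param gm A genotype table.
#' @return A filtered `geno_tbl`. A zero-locus result triggers a warning,
#'   not an error.
#' @export
filter_complete_biallelic <- function(gm) {
  st <- locus_stats(gm)
  keep <- st$locus[st$biallelic & st$complete]
  if (length(keep) == 0) warning("no complete biallelic loci retained")
  out <- gm[gm$locus %in% keep, ]
  new_geno_tbl(out, keep, individual_ids(gm))
}

#' Keep one SNP site per RAD locus
#'
#' For matrices whose locus ids encode multi-SNP RAD loci as
#' `<radlocus><sep><offset>`, keeps the first site of each RAD locus.
#' Ids without the separator are their own RAD locus.
#'
#' @param gm A genotype table.
#' @param sep Separator between RAD locus id and site offset.
#' @return A filtered `geno_tbl`.
#' @export
filter_one_snp_per_locus <- function(gm, sep = ":") {
  lids <- locus_ids(gm)
  rad <- stringr::str_split_fixed(lids, stringr::fixed(sep), 2)[, 1]
  keep <- lids[!duplicated(rad)]
  new_geno_tbl(gm[gm$locus %in% keep, ], keep, individual_ids(gm))
}

#' Split an individual's genotypes into two haplotype vectors
#'
#' Diploid calls are unphased; the split follows storage order, so `hapA`
#' takes the first-stored allele at every locus and `hapB` the second.
#' Homozygous loci give identical entries in both. This arbitrary-but-fixed
#' pairing is what lets each ABBA/BABA combination be "run twice to account
#' for both alleles" deterministically.
#'
#' @param gm A genotype table (complete and biallelic; run
#'   [filter_complete_biallelic()] first).
#' @param individual Individual id.
#' @return A tibble with columns `locus`, `hapA`, `hapB` in matrix locus
#'   order.
#' @export
split_haplotypes <- function(gm, individual) {
  if (!individual %in% individual_ids(gm)) {
    stop("unknown individual: ", individual)
  }
  x <- gm[gm$individual == individual, ]
  x <- x[match(locus_ids(gm), x$locus), ]
  if (anyNA(x$a1)) {
    stop("missing call(s) for ", individual,
         "; apply filter_complete_biallelic() first")
  }
  tibble::tibble(locus = x$locus, hapA = x$a1, hapB = x$a2)
}

# loci x individuals character matrices of the two stored alleles
geno_matrices <- function(gm) {
  lids <- locus_ids(gm)
  inds <- individual_ids(gm)
  li <- match(gm$locus, lids)
  ii <- match(gm$individual, inds)
  a1 <- matrix(NA_character_, length(lids), length(inds),
               dimnames = list(lids, inds))
  a2 <- a1
  a1[cbind(li, ii)] <- gm$a1
  a2[cbind(li, ii)] <- gm$a2
  list(a1 = a1, a2 = a2)
}

# 0/1 integer haplotype matrices for a complete biallelic matrix; allele
# coded 1 is the lexicographically later label (coding is arbitrary but
# consistent across individuals, which is all pattern counting needs)
recode_biallelic <- function(gm) {
  st <- locus_stats(gm)
  if (!all(st$biallelic & st$complete)) {
    stop("matrix must be complete and biallelic; ",
         "apply filter_complete_biallelic() first")
  }
  mats <- geno_matrices(gm)
  a0 <- vapply(st$alleles, `[`, character(1), 1L)
  a1lab <- vapply(st$alleles, `[`, character(1), 2L)
  lab1 <- a1lab[row(mats$a1)]  # per-cell label of the allele coded 1
  hapA <- 1L * (mats$a1 == lab1)
  hapB <- 1L * (mats$a2 == lab1)
  list(hapA = hapA, hapB = hapB,
       alleles = tibble::tibble(locus = st$locus, allele0 = a0,
                                allele1 = a1lab))
}
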