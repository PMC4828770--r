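# Build a genotype table from "A/G"-style strings: a named list of loci,
# each a character vector of calls in `individuals` order ("./." = missing).
make_geno <- function(calls, individuals) {
  rows <- lapply(names(calls), function(l) {
    parts <- strsplit(calls[[l]], "/", fixed = TRUE)
    data.frame(
      locus = l,
      individual = individuals,
      a1 = vapply(parts, `[`, character(1), 1),
      a2 = vapply(parts, `[`, character(1), 2)
    )
  })
  df <- do.call(rbind, rows)
  df$a1[df$a1 == "."] <- NA
  df$a2[df$a2 == "."] <- NA
  as_geno_tbl(df)
}

popmap_of <- function(...) {
  groups <- list(...)
  tibble::tibble(
    individual = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
}

# Independent per-site enumeration of ABBA/BABA patterns: explicit loop,
# classifying each site from its full allele multiset.
oracle_site_patterns <- function(h1, h2, h3, h4) {
  n_abba <- 0L; n_baba <- 0L; n_other <- 0L
  for (i in seq_along(h1)) {
    s <- c(h1[i], h2[i], h3[i], h4[i])
    if (length(unique(s)) == 2 && s[1] == s[4] && s[2] == s[3]) {
      n_abba <- n_abba + 1L
    } else if (length(unique(s)) == 2 && s[2] == s[4] && s[1] == s[3]) {
      n_baba <- n_baba + 1L
    } else {
      n_other <- n_other + 1L
    }
  }
  c(n_abba = n_abba, n_baba = n_baba, n_other = n_other)
}

# Exhaustive per-group allele-set scan for diagnostic loci.
oracle_diagnostic <- function(gm, pm, ga, gb) {
  inds_a <- pm$individual[pm$group == ga]
  inds_b <- pm$individual[pm$group == gb]
  keep <- character(0)
  for (l in locus_ids(gm)) {
    sub <- gm[gm$locus == l, ]
    als_a <- unique(c(sub$a1[sub$individual %in% inds_a],
                      sub$a2[sub$individual %in% inds_a]))
    als_b <- unique(c(sub$a1[sub$individual %in% inds_b],
                      sub$a2[sub$individual %in% inds_b]))
    als_a <- als_a[!is.na(als_a)]; als_b <- als_b[!is.na(als_b)]
    if (length(als_a) == 1 && length(als_b) == 1 && als_a != als_b) {
      keep <- c(keep, l)
    }
  }
  keep
}

# The 3-locus two-group toy whose Weir-Cockerham theta was hand-computed
# with exact rational arithmetic: theta = (1/2) / (21/20) = 10/21.
wc_toy <- function() {
  gm <- make_geno(list(
    L1 = c("A/A", "A/G", "A/A", "G/G", "A/G"),
    L2 = c("A/G", "G/G", "A/G", "A/A", "A/G"),
    L3 = c("A/A", "A/A", "A/G", "G/G", "G/G")
  ), c("x1", "x2", "x3", "y1", "y2"))
  pm <- popmap_of(X = c("x1", "x2", "x3"), Y = c("y1", "y2"))
  list(gm = gm, pm = pm, theta = 10 / 21)
}
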