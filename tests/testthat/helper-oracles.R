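# Independent brute-force oracles used to pin down the package's
# implementations, plus small fixture builders. The oracles re-derive each
# result from the definition, not from the package's code path.

# naive single-linkage agglomeration: keeps an explicit list of clusters and
# at every step scans all cross-cluster gene pairs for the global minimum,
# breaking ties on the smallest (sorted-label) member index pair
oracle_single_linkage <- function(d) {
  labels <- sort(rownames(d))
  d <- d[labels, labels]
  clusters <- as.list(seq_along(labels))
  heights <- numeric(0)
  partitions <- list()   # partition after each merge, as sorted membership
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      for (i in clusters[[a]]) for (j in clusters[[b]]) {
        cand <- list(h = d[i, j], key = sort(c(i, j)), a = a, b = b)
        if (is.null(best) || cand$h < best$h ||
            (cand$h == best$h &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
          best <- cand
      }
    }
    heights <- c(heights, best$h)
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters <- clusters[-c(best$a, best$b)]
    clusters[[length(clusters) + 1L]] <- merged
    partitions[[length(partitions) + 1L]] <-
      canonical_partition(clusters, labels)
  }
  list(heights = heights, partitions = partitions, labels = labels)
}

# canonical string form of a partition for equality checks
canonical_partition <- function(clusters, labels) {
  paste(sort(vapply(clusters, function(cl)
    paste(labels[cl], collapse = ","), character(1))), collapse = ";")
}

partition_from_cut <- function(assignment) {
  canonical_partition(split(seq_along(assignment), assignment),
                      names(assignment))
}

# greedy informative-marker selection, re-derived from its definition
oracle_select <- function(snp_ids, p, r2, r2_max, p_include) {
  ord <- order(p, snp_ids)
  acc <- character(0)
  for (i in ord) {
    if (p[i] >= p_include) next
    ok <- TRUE
    for (a in acc) if (r2[snp_ids[i], a] >= r2_max) ok <- FALSE
    if (ok) acc <- c(acc, snp_ids[i])
  }
  acc
}

# small expression tibble fixture: explicit per-gene profiles
make_expr <- function(profiles, brain = "donor1", regions = NULL) {
  genes <- names(profiles)
  n_r <- length(profiles[[1]])
  region_ids <- sprintf("R%03d", seq_len(n_r))
  expr <- dplyr::bind_rows(lapply(genes, function(g)
    tibble::tibble(brain = brain, probe = paste0(g, "_p1"), gene = g,
                   region_id = region_ids, value = profiles[[g]])))
  expr
}

# symmetric cubic grid with a voxel centre exactly at the origin
make_grid <- function(n_half = 5, spacing = 2) {
  n <- 2L * n_half + 1L
  voxel_map(array(0, c(n, n, n)), origin = rep(-n_half * spacing, 3),
            spacing = spacing)
}

small_genotypes <- function(dosages, phenotype, genes = NULL) {
  snps <- colnames(dosages)
  genotype_data(dosages, phenotype,
                tibble::tibble(snp_id = snps,
                               gene = genes %||% rep("G01", length(snps)),
                               chrom = 1L, pos = seq_along(snps)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
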