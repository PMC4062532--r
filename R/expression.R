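#' Collapse probe-level expression to gene level
#'
#' Microarray surveys usually carry several probes per gene; downstream
#' clustering works at gene level. Each gene's value per region (and brain)
#' is the arithmetic mean of its probes, and genes are returned in
#' lexicographic order.
#'
#' @param expr Long tibble with columns `brain`, `probe`, `gene`,
#'   `region_id`, `value`.
#' @return Tibble with columns `brain`, `gene`, `region_id`, `value`, one
#'   row per gene/region/brain.
#' @export
collapse_probes <- function(expr) {
  req <- c("brain", "probe", "gene", "region_id", "value")
  if (!all(req %in% names(expr)))
    stopf("`expr` must have columns %s", paste(req, collapse = ", "))
  if (anyNA(expr$gene) || any(expr$gene == ""))
    stopf("every probe must map to exactly one gene symbol")
  # rowsum-based group means: (brain, gene, region) groups are numerous and
  # tiny, so grouped verbs are the bottleneck here
  key <- paste(expr$brain, expr$gene, expr$region_id, sep = "\r")
  sums <- rowsum(expr$value, key)
  cnt <- rowsum(rep(1, nrow(expr)), key)
  first <- !duplicated(key)
  out <- tibble(brain = expr$brain[first], gene = expr$gene[first],
                region_id = expr$region_id[first],
                value = as.numeric(sums[match(key[first], rownames(sums))] /
                                     cnt[match(key[first], rownames(cnt))]))
  out[order(out$brain, out$gene, out$region_id), ]
}

#' Z-normalise each gene's expression across brain regions
#'
#' Standardises every gene row (per brain) to mean 0 and sample standard
#' deviation 1 (n - 1 denominator) across regions, so that values express
#' relative regional enrichment or depletion of that gene. Z-scoring is
#' idempotent.
#'
#' @param expr Long tibble with columns `brain`, `gene`, `region_id`,
#'   `value` (gene-level; run [collapse_probes()] first if needed).
#' @return The same tibble with `value` replaced by Z-scores.
#' @export
zscore_genes <- function(expr) {
  key <- paste(expr$brain, expr$gene, sep = "\r")
  n <- as.numeric(rowsum(rep(1, nrow(expr)), key))
  kn <- rownames(rowsum(rep(1, nrow(expr)), key))
  s1 <- as.numeric(rowsum(expr$value, key))
  s2 <- as.numeric(rowsum(expr$value^2, key))
  mu <- s1 / n
  sdv <- sqrt(pmax(s2 - n * mu^2, 0) / (n - 1))
  bad <- sdv < 1e-12 | !is.finite(sdv)
  if (any(bad)) {
    genes <- unique(vapply(strsplit(kn[bad], "\r", fixed = TRUE), `[`,
                           character(1), 2L))
    stopf("cannot standardise constant expression for gene(s): %s",
          paste(genes, collapse = ", "))
  }
  i <- match(key, kn)
  mutate(expr, value = (.data$value - mu[i]) / sdv[i])
}

# genes x regions matrix for one brain, genes sorted lexicographically
expr_to_matrix <- function(expr) {
  wide <- expr |>
    arrange(.data$gene, .data$region_id) |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "region_id",
                       values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene
  if (anyNA(m)) stopf("expression matrix has missing gene/region entries")
  m
}

# Single-linkage (nearest-neighbour) agglomeration on a distance matrix with
# deterministic tie-breaking: labels are sorted lexicographically up front
# and, among equidistant cluster pairs, the pair containing the smallest
# member indices merges first. Returns an hclust-compatible object.
single_linkage <- function(d) {
  labels <- rownames(d)
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]
  n <- nrow(d)
  dd <- d
  diag(dd) <- Inf
  active <- seq_len(n)          # columns of dd still live
  id <- -seq_len(n)             # hclust node id per live cluster
  member_min <- seq_len(n)      # smallest original index, for tie-breaks
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    sub <- dd[active, active, drop = FALSE]
    hmin <- min(sub)
    hit <- which(sub == hmin, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    key <- order(member_min[active][hit[, 1]], member_min[active][hit[, 2]])
    a <- active[hit[key[1], 1]]
    b <- active[hit[key[1], 2]]
    pair <- sort(c(id[a], id[b]))
    merge[step, ] <- pair
    height[step] <- hmin
    # single linkage: distance to the union is the min of the parts
    dd[a, ] <- dd[, a] <- pmin(dd[a, ], dd[b, ])
    dd[a, a] <- Inf
    id[a] <- step
    member_min[a] <- min(member_min[a], member_min[b])
    active <- setdiff(active, b)
  }
  out <- structure(
    list(merge = merge, height = height, order = integer(n), labels = labels,
         method = "single", dist.method = "1 - pearson"),
    class = "hclust")
  out$order <- hclust_order(merge, n)
  out
}

# leaf order by traversal of the merge tree (for plotting compatibility)
hclust_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' Cluster genes by regional expression profile
#'
#' Agglomerative single-linkage (nearest-neighbour) hierarchical clustering
#' of genes under the correlation distance `d(g, h) = 1 - r(g, h)` across
#' brain regions, for one donor brain. The dendrogram can be cut three ways:
#' at an explicit number of clusters `k`, at a correlation-distance height
#' `cut_height` (the default, 0.7, groups genes linked at pairwise `r` above
#' 0.3 and leaves weakly correlated genes as singletons), or at the `k` in
#' 2..8 maximising the mean silhouette width (`cut = "silhouette"`).
#'
#' @param expr Z-scored gene-level tibble (`brain`, `gene`, `region_id`,
#'   `value`) containing exactly one brain.
#' @param k Number of clusters for `cut = "k"`.
#' @param cut_height Height for `cut = "height"`.
#' @param cut Cut rule: `"height"` (default), `"k"`, or `"silhouette"`.
#' @return Object of class `gene_dendrogram`: list with `tree` (an `hclust`
#'   object), `labels` (tibble `gene`, `cluster` integer codes) and `dist`
#'   (the distance matrix).
#' @export
cluster_genes <- function(expr, k = NULL, cut_height = 0.7,
                          cut = c("height", "k", "silhouette")) {
  cut <- match.arg(cut)
  if (!is.null(k)) cut <- "k"
  if (length(unique(expr$brain)) != 1L)
    stopf("`expr` must contain exactly one brain; filter first")
  m <- expr_to_matrix(expr)
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 genes to cluster")
  d <- 1 - cor(t(m))
  tree <- single_linkage(d)
  cl <- switch(cut,
    height = cutree(tree, h = cut_height),
    k = {
      if (is.null(k) || k < 2 || k > n)
        stopf("`k` must lie in [2, %d]", n)
      cutree(tree, k = k)
    },
    silhouette = {
      ks <- 2:min(8L, n - 1L)
      sw <- vapply(ks, function(kk) {
        labs <- cutree(tree, k = kk)
        mean(cluster::silhouette(labs, stats::as.dist(d))[, 3])
      }, numeric(1))
      cutree(tree, k = ks[which.max(sw)])
    })
  structure(
    list(tree = tree,
         labels = tibble(gene = names(cl), cluster = as.integer(cl)),
         dist = d),
    class = "gene_dendrogram")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("<gene_dendrogram> %d genes, %d clusters (single linkage, 1 - r)\n",
              nrow(x$labels), length(unique(x$labels$cluster))))
  invisible(x)
}

#' @export
tidy.gene_dendrogram <- function(x, ...) x$labels

#' Consensus clusters across two donor brains
#'
#' Two genes are consensus-co-clustered only if they are co-clustered in
#' both brains; consensus clusters are the connected components of that
#' relation (equivalently, groups of genes with identical label pairs) with
#' at least `min_cluster_size` members, and every other gene is declared
#' unclustered. This is the reproducibility rule that turns two per-donor
#' dendrogram cuts into one conservative partition.
#'
#' @param labels_brain1,labels_brain2 Tibbles with columns `gene`, `cluster`
#'   (e.g. `$labels` of [cluster_genes()]) over the same gene universe.
#' @param min_cluster_size Minimum consensus cluster size (default 2).
#' @return Object of class `consensus_clusters`: tibble with columns `gene`
#'   and `cluster` (`"C1"`, `"C2"`, ... ordered by decreasing size, `NA` for
#'   unclustered genes).
#' @export
consensus_clusters <- function(labels_brain1, labels_brain2,
                               min_cluster_size = 2) {
  g1 <- sort(labels_brain1$gene)
  g2 <- sort(labels_brain2$gene)
  if (!identical(g1, g2)) stopf("gene universes differ between brains")
  df <- left_join(labels_brain1, labels_brain2, by = "gene",
                  suffix = c("_1", "_2"))
  combo <- paste(df$cluster_1, df$cluster_2, sep = "|")
  sizes <- table(combo)
  keep <- names(sizes)[sizes >= min_cluster_size]
  cl <- ifelse(combo %in% keep, combo, NA_character_)
  # relabel kept groups C1.. by decreasing size, ties by smallest gene
  grp <- split(df$gene, cl)
  ord <- order(-lengths(grp), vapply(grp, min, character(1)))
  newname <- setNames(sprintf("C%d", seq_along(ord)), names(grp)[ord])
  out <- tibble(gene = df$gene,
                cluster = unname(newname[cl]))
  class(out) <- c("consensus_clusters", class(out))
  out
}

#' @export
tidy.consensus_clusters <- function(x, ...) {
  tibble(gene = x$gene, cluster = x$cluster)
}

#' @export
glance.consensus_clusters <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_clusters = length(unique(stats::na.omit(x$cluster))),
         n_clustered = sum(!is.na(x$cluster)),
         n_unclustered = sum(is.na(x$cluster)))
}

#' Agreement between a recovered and a reference partition
#'
#' Adjusted Rand index between two gene partitions, treating unassigned
#' (`NA`) genes as singleton classes so that correctly leaving a noise gene
#' unclustered counts as agreement.
#'
#' @param truth,estimate Tibbles with columns `gene`, `cluster` (`NA`
#'   allowed).
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
cluster_recovery <- function(truth, estimate) {
  df <- left_join(truth, estimate, by = "gene", suffix = c("_t", "_e"))
  lab <- function(cl, tag) ifelse(is.na(cl), paste0(".single_", tag, "_",
                                                    seq_along(cl)), cl)
  mclust::adjustedRandIndex(lab(df$cluster_t, "t"), lab(df$cluster_e, "e"))
}

#' Cluster mean-Z voxel map with hemisphere folding and blurring
#'
#' For one consensus cluster, averages the Z-scores of its member genes per
#' region (across brains), averages homologous left/right regions and
#' mirrors the folded value to both hemispheres, then renders the regional
#' values onto a voxel grid: each region is splatted to its nearest voxel
#' and blurred with an isotropic Gaussian of the given FWHM, normalised so
#' an isolated region's peak retains its Z value.
#'
#' @param expr Z-scored gene-level expression tibble (both brains allowed).
#' @param assignment A [consensus_clusters()] result (or any tibble `gene`,
#'   `cluster`).
#' @param cluster Cluster label to map (e.g. `"C1"`).
#' @param regions Region table (`region_id`, `x`, `y`, `z`, `hemisphere`).
#' @param grid A `voxel_map` supplying the output grid and mask.
#' @param fwhm_mm Blurring kernel FWHM in mm (default 12).
#' @param mirror_tol_mm Max distance (mm) between a region and its mirrored
#'   homologue for the two to be averaged (default 2).
#' @return A `voxel_map` of cluster mean-Z values, mirror-symmetric in x.
#' @export
cluster_zmap <- function(expr, assignment, cluster, regions,
                         grid = gen_brain_mask(), fwhm_mm = 12,
                         mirror_tol_mm = 2) {
  genes <- assignment$gene[!is.na(assignment$cluster) &
                             assignment$cluster == cluster]
  if (length(genes) == 0L) stopf("cluster '%s' is empty", cluster)
  vals <- expr |>
    filter(.data$gene %in% genes) |>
    group_by(.data$region_id) |>
    summarise(mean_z = mean(.data$value), .groups = "drop") |>
    left_join(regions, by = "region_id")

  xyz <- as.matrix(vals[, c("x", "y", "z")])
  z <- vals$mean_z
  # fold: average each region with its nearest mirrored homologue, then
  # place the folded value at both (+x) and (-x); midline stays put
  folded_xyz <- matrix(numeric(0), 0, 3)
  folded_z <- numeric(0)
  used <- rep(FALSE, nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    if (used[i]) next
    if (abs(xyz[i, 1]) <= 1e-9) {        # midline
      folded_xyz <- rbind(folded_xyz, xyz[i, ])
      folded_z <- c(folded_z, z[i])
      used[i] <- TRUE
      next
    }
    mirror <- c(-xyz[i, 1], xyz[i, 2], xyz[i, 3])
    d <- sqrt(colSums((t(xyz) - mirror)^2))
    d[used] <- Inf
    d[i] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= mirror_tol_mm) {
      v <- (z[i] + z[j]) / 2
      used[c(i, j)] <- TRUE
    } else {
      v <- z[i]
      used[i] <- TRUE
    }
    folded_xyz <- rbind(folded_xyz, xyz[i, ], mirror)
    folded_z <- c(folded_z, v, v)
  }
  # splat to nearest voxel centre, then unit-peak Gaussian blur
  snapped <- voxel_coords(grid, coords_to_index(grid, folded_xyz))
  splat_gaussian(grid, snapped, folded_z, fwhm_to_sigma(fwhm_mm))
}

#' Extract expression peaks and troughs from a voxel map
#'
#' Finds local maxima with value `>= z_threshold` and local minima with
#' value `<= -z_threshold` (26-neighbourhood, within the mask), then greedily
#' retains them in descending `|value|` order subject to a minimum pairwise
#' separation.
#'
#' @param map A `voxel_map` (Z units).
#' @param z_threshold Positive threshold on `|value|` (default 2).
#' @param min_separation_mm Minimum distance between retained extrema
#'   (default 12 mm).
#' @return Tibble with columns `x`, `y`, `z`, `value`, `sign` (`"+"`/`"-"`),
#'   possibly empty.
#' @export
extract_extrema <- function(map, z_threshold = 2, min_separation_mm = 12) {
  if (z_threshold <= 0) stopf("`z_threshold` must be > 0")
  d <- dim(map$data)
  base <- array(NA_real_, d + 2L)
  base[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- map$data
  nb_max <- array(-Inf, d)
  nb_min <- array(Inf, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    sh <- base[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj,
               (2:(d[3] + 1)) + dk, drop = FALSE]
    dim(sh) <- d
    nb_max <- pmax(nb_max, sh, na.rm = TRUE)
    nb_min <- pmin(nb_min, sh, na.rm = TRUE)
  }
  v <- map$data
  is_peak <- map$mask & v >= z_threshold & v >= nb_max
  is_trough <- map$mask & v <= -z_threshold & v <= nb_min
  idx <- c(which(is_peak), which(is_trough))
  if (length(idx) == 0L)
    return(tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                  value = numeric(0), sign = character(0)))
  xyz <- voxel_coords(map, idx)
  cand <- tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], value = v[idx],
                 sign = rep(c("+", "-"), c(sum(is_peak), sum(is_trough))))
  cand <- cand[order(-abs(cand$value), cand$x, cand$y, cand$z), ]
  kept <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    if (nrow(kept) == 0L ||
        all(sqrt((kept$x - cand$x[r])^2 + (kept$y - cand$y[r])^2 +
                   (kept$z - cand$z[r])^2) >= min_separation_mm))
      kept <- bind_rows(kept, cand[r, ])
  }
  kept
}
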