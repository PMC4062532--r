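test_that("probe collapsing averages region-wise and validates mapping", {
  expr <- tibble::tibble(
    brain = "donor1",
    probe = c("p1", "p1", "p2", "p2"),
    gene = "GA",
    region_id = c("R1", "R2", "R1", "R2"),
    value = c(1, 3, 3, 5))
  out <- collapse_probes(expr)
  expect_equal(out$value, c(2, 4))
  # identical probes reproduce either one
  expr2 <- dplyr::mutate(expr, value = rep(c(1, 3), 2))
  expect_equal(collapse_probes(expr2)$value, c(1, 3))
  expect_error(collapse_probes(dplyr::mutate(expr, gene = NA)), "gene")
})

test_that("many-to-one probe tables collapse to one row per gene", {
  # 58 genes carrying 105 probes in total
  genes <- sprintf("G%02d", 1:58)
  n_probes <- c(rep(2, 47), rep(1, 11))
  expect_equal(sum(n_probes), 105)
  expr <- dplyr::bind_rows(purrr::map2(genes, n_probes, function(g, np)
    tibble::tibble(brain = "donor1",
                   probe = sprintf("%s_p%d", g, rep(1:np, each = 3)),
                   gene = g, region_id = rep(c("R1", "R2", "R3"), np),
                   value = rnorm(3 * np))))
  out <- collapse_probes(expr)
  expect_equal(length(unique(out$gene)), 58)
  expect_equal(nrow(out), 58 * 3)
  expect_equal(unique(out$gene), sort(genes))
})

test_that("z-scoring standardises, is idempotent and flags constants", {
  expr <- make_expr(list(GA = c(1, 2, 3)))
  expect_equal(zscore_genes(expr)$value, c(-1, 0, 1))
  set.seed(42)
  r <- make_expr(list(GB = rnorm(50, 10, 4)))
  z <- zscore_genes(r)
  expect_equal(mean(z$value), 0, tolerance = 1e-12)
  expect_equal(sd(z$value), 1, tolerance = 1e-12)
  expect_equal(zscore_genes(z)$value, z$value, tolerance = 1e-12)
  expect_error(zscore_genes(make_expr(list(GC = rep(2, 5)))), "GC")
})

test_that("single linkage merges perfect correlates at height zero", {
  expr <- make_expr(list(GA = c(1, 2, 3, 5), GB = c(2, 4, 6, 10),
                         GC = c(5, 1, 0, 2)))
  dend <- cluster_genes(zscore_genes(expr), k = 2)
  expect_equal(dend$tree$height[1], 0, tolerance = 1e-12)
  lab <- dend$labels
  expect_equal(lab$cluster[lab$gene == "GA"], lab$cluster[lab$gene == "GB"])
  expect_false(lab$cluster[lab$gene == "GC"] ==
                 lab$cluster[lab$gene == "GA"])
})

test_that("single linkage matches the exhaustive nearest-pair oracle", {
  set.seed(7)
  for (case in 1:40) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(n * 15), n)
    rownames(m) <- sprintf("g%02d", sample(n))
    d <- 1 - cor(t(m))
    ours <- neurexmap:::single_linkage(d)
    orc <- oracle_single_linkage(d)
    expect_equal(ours$height, orc$heights, tolerance = 1e-12)
    for (k in seq_len(n - 1)) {
      cut <- cutree(ours, k = k)
      expect_identical(partition_from_cut(cut), orc$partitions[[n - k]])
    }
  }
})

test_that("single linkage agrees with stats::hclust on merge heights", {
  set.seed(11)
  m <- matrix(rnorm(20 * 30), 20)
  rownames(m) <- sprintf("g%02d", 1:20)
  d <- 1 - cor(t(m))
  ours <- neurexmap:::single_linkage(d)
  ref <- stats::hclust(as.dist(d), method = "single")
  expect_equal(ours$height, ref$height, tolerance = 1e-12)
  for (k in c(2, 5, 10))
    expect_identical(partition_from_cut(cutree(ours, k = k)),
                     partition_from_cut(cutree(ref, k = k)))
})

test_that("merge order is invariant under monotone distance transforms", {
  set.seed(13)
  for (case in 1:10) {
    m <- matrix(rnorm(10 * 12), 10)
    rownames(m) <- sprintf("g%02d", 1:10)
    d <- 1 - cor(t(m))
    a <- neurexmap:::single_linkage(d)
    b <- neurexmap:::single_linkage(sqrt(d))   # monotone transform
    for (k in 2:9)
      expect_identical(partition_from_cut(cutree(a, k = k)),
                       partition_from_cut(cutree(b, k = k)))
  }
})

test_that("cutting planted-cluster genes at k = 3 recovers the truth", {
  sim <- gen_expression(sim_config(seed = 17))
  zs <- zscore_genes(collapse_probes(sim$expression))
  planted <- sim$truth$gene[!is.na(sim$truth$cluster)]
  d1 <- cluster_genes(dplyr::filter(zs, brain == "donor1",
                                    gene %in% planted), k = 3)
  truth <- dplyr::filter(sim$truth, gene %in% planted)
  est <- dplyr::mutate(d1$labels, cluster = as.character(cluster))
  expect_gte(cluster_recovery(truth, est), 0.9)
})

test_that("consensus is the intersection of co-membership across brains", {
  l1 <- tibble::tibble(gene = c("A", "B", "C", "D"), cluster = c(1, 1, 2, 2))
  # identical labelings reproduce the input partition
  same <- consensus_clusters(l1, l1, min_cluster_size = 2)
  expect_equal(sum(!is.na(same$cluster)), 4)
  expect_equal(length(unique(stats::na.omit(same$cluster))), 2)
  # C co-clusters with A in brain 2 but with D in brain 1: C drops out
  l2 <- tibble::tibble(gene = c("A", "B", "C", "D"), cluster = c(1, 1, 1, 2))
  cons <- consensus_clusters(l1, l2)
  expect_true(is.na(cons$cluster[cons$gene == "C"]))
  expect_true(is.na(cons$cluster[cons$gene == "D"]))
  expect_equal(sum(!is.na(cons$cluster)), 2)
  expect_error(
    consensus_clusters(l1, dplyr::mutate(l2, gene = c("A", "B", "C", "E"))),
    "universes")
})

test_that("cluster mean-Z maps follow the closed-form Gaussian kernel", {
  grid <- make_grid(n_half = 10, spacing = 2)
  regions <- tibble::tibble(region_id = "R1", structure_name = "s",
                            x = 0, y = 0, z = 0, hemisphere = "midline")
  expr <- tibble::tibble(brain = "donor1", gene = "GA", region_id = "R1",
                         value = 2)
  asg <- tibble::tibble(gene = "GA", cluster = "C1")
  vm <- cluster_zmap(expr, asg, "C1", regions, grid = grid, fwhm_mm = 12)
  sigma <- 12 / sqrt(8 * log(2))
  i0 <- neurexmap:::coords_to_index(vm, matrix(c(0, 0, 0), 1))
  i6 <- neurexmap:::coords_to_index(vm, matrix(c(6, 0, 0), 1))
  expect_equal(max(vm$data), 2, tolerance = 1e-12)
  expect_equal(vm$data[i0], 2)
  expect_equal(vm$data[i6], 2 * exp(-36 / (2 * sigma^2)), tolerance = 1e-12)
  expect_error(cluster_zmap(expr, asg, "C9", regions, grid), "empty")
})

test_that("hemisphere folding averages homologues and mirrors the value", {
  grid <- make_grid(n_half = 15, spacing = 2)
  regions <- tibble::tibble(
    region_id = c("R1", "R2"), structure_name = c("a", "a"),
    x = c(20, -20), y = 0, z = 0, hemisphere = c("right", "left"))
  expr <- tibble::tibble(brain = "donor1", gene = "GA",
                         region_id = c("R1", "R2"), value = c(1, 3))
  asg <- tibble::tibble(gene = "GA", cluster = "C1")
  vm <- cluster_zmap(expr, asg, "C1", regions, grid = grid, fwhm_mm = 12)
  iR <- neurexmap:::coords_to_index(vm, matrix(c(20, 0, 0), 1))
  iL <- neurexmap:::coords_to_index(vm, matrix(c(-20, 0, 0), 1))
  expect_equal(vm$data[iR], 2, tolerance = 1e-6)
  expect_equal(vm$data[iL], 2, tolerance = 1e-6)
  # exact mirror symmetry of the whole map
  expect_equal(vm$data, vm$data[dim(vm$data)[1]:1, , ], tolerance = 1e-12)
})

test_that("synthetic cluster maps are mirror-symmetric in x", {
  sim <- gen_expression(sim_config(n_regions = 80, n_genes = 10,
                                   cluster_sizes = c(4), seed = 19L))
  zs <- zscore_genes(collapse_probes(sim$expression))
  asg <- tibble::tibble(gene = sim$truth$gene, cluster = sim$truth$cluster)
  grid <- gen_brain_mask(8)
  vm <- cluster_zmap(zs, asg, "C1", sim$regions, grid = grid)
  expect_equal(vm$data, vm$data[dim(vm$data)[1]:1, , ], tolerance = 1e-9)
  # all-zero input maps to an all-zero field
  expr0 <- dplyr::mutate(zs, value = 0)
  vm0 <- cluster_zmap(expr0, asg, "C1", sim$regions, grid = grid)
  expect_equal(max(abs(vm0$data)), 0)
})

test_that("extremum extraction thresholds and separates peaks greedily", {
  grid <- make_grid(n_half = 12, spacing = 1)
  bump <- function(center, peak, sigma = 3) {
    xyz <- neurexmap:::voxel_coords(grid)
    d2 <- rowSums(sweep(xyz, 2, center)^2)
    array(peak * exp(-d2 / (2 * sigma^2)), dim(grid$data))
  }
  one <- voxel_map(bump(c(0, 0, 0), 3), grid$origin, grid$spacing)
  pk <- extract_extrema(one, z_threshold = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$x, pk$y, pk$z), c(0, 0, 0))
  expect_equal(pk$sign, "+")
  # two sharp bumps 5 mm apart with 10 mm separation: larger one only
  two <- voxel_map(bump(c(-2, 0, 0), 3, sigma = 1.5) +
                     bump(c(3, 0, 0), 2.5, sigma = 1.5),
                   grid$origin, grid$spacing)
  pk2 <- extract_extrema(two, z_threshold = 2, min_separation_mm = 10)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$x, -2, tolerance = 1)
  # negative trough detected with sign "-"
  neg <- voxel_map(-bump(c(0, 0, 0), 3), grid$origin, grid$spacing)
  expect_equal(extract_extrema(neg, 2)$sign, "-")
  # threshold above the global maximum: empty table
  expect_equal(nrow(extract_extrema(one, z_threshold = 5)), 0)
  expect_error(extract_extrema(one, z_threshold = 0), "threshold")
})
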