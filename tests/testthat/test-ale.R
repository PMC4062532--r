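test_that("the MNI-to-Talairach transform applies the piecewise mapping", {
  expect_equal(mni_to_tal(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(mni_to_tal(c(0, 0, 10)), c(0, 0.46, 9.189))
  expect_equal(mni_to_tal(c(10, 0, 0)), c(9.9, 0, 0))
  # below the AC-PC line the z coefficients change
  expect_equal(mni_to_tal(c(0, 10, -10)),
               c(0, 0.9688 * 10 - 0.042 * 10, -0.0485 * 10 - 8.390))
  m <- mni_to_tal(rbind(c(0, 0, 10), c(10, 0, 0)))
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m[1, ], c(0, 0.46, 9.189))
})

test_that("kernel width interpolates from 9 to 8.5 mm with sample size", {
  expect_equal(fwhm_for_study(12, n_range = c(12, 100)), 9)
  expect_equal(fwhm_for_study(100, n_range = c(12, 100)), 8.5)
  expect_equal(fwhm_for_study(56, n_range = c(12, 100)), 8.75)
  expect_equal(fwhm_for_study(5, n_range = c(12, 100)), 9)    # clamped
  expect_equal(fwhm_for_study(400, n_range = c(12, 100)), 8.5)
  n <- 10:110
  expect_true(all(diff(fwhm_for_study(n)) <= 0))
})

test_that("ALE is the probabilistic union of per-focus kernels", {
  grid <- make_grid(n_half = 8, spacing = 2)
  # choose sigma so the focus voxel gets exactly p = 0.5:
  # vv / (2 pi s^2)^1.5 = 0.5  =>  s = sqrt((2 vv)^(2/3) / (2 pi))
  vv <- grid$spacing^3
  s <- sqrt((2 * vv)^(2 / 3) / (2 * pi))
  fw <- s * sqrt(8 * log(2))
  studies <- tibble::tibble(study_id = c("a", "b"), n_subjects = 20,
                            x = 0, y = 0, z = 0)
  m <- ale_map(studies, grid, fwhm_range = c(fw, fw))
  i0 <- neurexmap:::coords_to_index(m, matrix(0, 1, 3))
  expect_equal(m$data[i0], 0.75, tolerance = 1e-9)      # 1 - 0.5^2

  # single focus: ALE equals its modelled-activation map; closed-form peak
  one <- ale_map(studies[1, ], grid, fwhm_range = c(9, 9))
  s9 <- 9 / sqrt(8 * log(2))
  expect_equal(max(one$data), vv / (2 * pi * s9^2)^1.5, tolerance = 1e-9)
  xyz <- neurexmap:::voxel_coords(grid)
  d2 <- rowSums(xyz^2)
  ma <- pmin(vv / (2 * pi * s9^2)^1.5 * exp(-d2 / (2 * s9^2)), 1)
  expect_equal(as.numeric(one$data), ma, tolerance = 1e-9)
})

test_that("ALE matches a direct union computation and its bounds", {
  grid <- make_grid(n_half = 6, spacing = 2)
  set.seed(5)
  studies <- tibble::tibble(
    study_id = rep(c("s1", "s2", "s3"), each = 2),
    n_subjects = rep(c(15, 50, 90), each = 2),
    x = runif(6, -8, 8), y = runif(6, -8, 8), z = runif(6, -8, 8))
  m <- ale_map(studies, grid)
  # direct product over per-focus kernels, computed independently
  vv <- grid$spacing^3
  xyz <- neurexmap:::voxel_coords(grid)
  sig <- (9 + (pmin(pmax((studies$n_subjects - 12) / 88, 0), 1)) * -0.5) /
    sqrt(8 * log(2))
  pk <- sapply(seq_len(6), function(k) {
    d2 <- (xyz[, 1] - studies$x[k])^2 + (xyz[, 2] - studies$y[k])^2 +
      (xyz[, 3] - studies$z[k])^2
    pmin(vv / (2 * pi * sig[k]^2)^1.5 * exp(-d2 / (2 * sig[k]^2)), 1)
  })
  direct <- 1 - apply(1 - pk, 1, prod)
  expect_equal(as.numeric(m$data), direct, tolerance = 1e-9)
  # union bound and single-kernel lower bound
  expect_true(all(m$data <= pmin(1, rowSums(pk)) + 1e-12))
  expect_true(all(sweep(pk, 1, as.numeric(m$data), `-`) <= 1e-12))
  # focus order is irrelevant; adding a focus never decreases ALE
  shuf <- ale_map(studies[sample(6), ], grid)
  expect_equal(m$data, shuf$data, tolerance = 1e-12)
  less <- ale_map(studies[1:5, ], grid)
  expect_true(all(m$data - less$data >= -1e-12))
})

test_that("by-study pooling unions modelled-activation maps per study", {
  grid <- make_grid(n_half = 5, spacing = 2)
  studies <- tibble::tibble(study_id = c("s1", "s1", "s2"), n_subjects = 20,
                            x = c(0, 2, 0), y = 0, z = 0)
  by_study <- ale_map(studies, grid, pooling = "by_study")
  ma1 <- ale_map(studies[1:2, ], grid)   # one study: union of its foci
  ma2 <- ale_map(studies[3, ], grid)
  expect_equal(as.numeric(by_study$data),
               as.numeric(1 - (1 - ma1$data) * (1 - ma2$data)),
               tolerance = 1e-12)
})

test_that("pooled permutation null yields corrected empirical p-values", {
  grid <- make_grid(n_half = 4, spacing = 4)
  null <- permutation_null(3, per_focus_fwhm = 9, mask = grid, n_perm = 20,
                           seed = 9L)
  nn <- length(null$values)
  expect_equal(nn, 20 * sum(grid$mask))
  obs <- voxel_map(array(0, dim(grid$data)), grid$origin, grid$spacing)
  p0 <- ale_p_map(obs, null)
  expect_equal(unique(as.numeric(p0$data)), 1)           # ALE 0 -> p = 1
  obs$data[1] <- 1                                       # above any null
  p1 <- ale_p_map(obs, null)
  expect_equal(p1$data[1], 1 / (nn + 1))
  expect_identical(permutation_null(3, 9, grid, 5, seed = 4L)$values,
                   permutation_null(3, 9, grid, 5, seed = 4L)$values)
  expect_error(permutation_null(3, 9, grid, n_perm = 0), "n_perm")
})

test_that("FDR step-up matches the worked example and p.adjust", {
  expect_equal(fdr_threshold(c(0.001, 0.02, 0.03, 0.5), q = 0.05), 0.03)
  expect_equal(fdr_threshold(rep(1, 10)), 0)
  expect_error(fdr_threshold(numeric(0)), "empty")
  expect_error(fdr_threshold(c(0.5, 1.2)), "0, 1")
  set.seed(3)
  for (case in 1:200) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    cut <- fdr_threshold(p, q)
    expect_identical(p <= cut, p.adjust(p, "BH") <= q)
  }
})

test_that("cluster extraction honours 26-connectivity and minimum extent", {
  d <- c(12L, 12L, 12L)
  ale <- voxel_map(array(runif(prod(d), 0.01, 0.02), d), c(0, 0, 0), 2)
  fg27 <- array(FALSE, d); fg27[2:4, 2:4, 2:4] <- TRUE       # 216 mm^3
  expect_equal(nrow(cluster_extract(fg27, ale)), 0)
  fg28 <- fg27; fg28[5, 2, 2] <- TRUE                        # 224 mm^3
  out <- cluster_extract(fg28, ale)
  expect_equal(nrow(out), 1)
  expect_equal(out$volume_mm3, 224)
  expect_equal(out$peak_ale, max(ale$data[fg28]))
  # diagonal touch is connected (26-neighbourhood) ...
  fgdiag <- fg28; fgdiag[5, 5, 5] <- TRUE
  expect_equal(nrow(cluster_extract(fgdiag, ale, min_volume_mm3 = 8)), 1)
  # ... a > 1 voxel gap is not
  fg2 <- fg28; fg2[8:10, 8:10, 8:10] <- TRUE
  expect_equal(nrow(cluster_extract(fg2, ale, min_volume_mm3 = 8)), 2)
})

test_that("peak ALE for a sparsely replicated locus sits in the reported band", {
  # two mid-sized studies reporting the same locus, the rest noise far away:
  # the union of two ~8.75 mm kernels peaks near 0.02
  grid <- make_grid(n_half = 10, spacing = 2)
  studies <- tibble::tibble(
    study_id = c("s1", "s2", "s3"), n_subjects = c(56, 56, 56),
    x = c(0, 0, 18), y = c(0, 0, 18), z = c(0, 0, -18))
  m <- ale_map(studies, grid)
  i0 <- neurexmap:::coords_to_index(m, matrix(0, 1, 3))
  expect_gt(m$data[i0], 0.015)
  expect_lt(m$data[i0], 0.022)
})
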