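#' MNI to Talairach coordinate transform
#'
#' Piecewise-linear (Brett) mapping from MNI to Talairach space, applied so
#' that foci published in either space can be analysed on one template:
#' `x' = 0.99 x`; above the AC-PC line (`z >= 0`)
#' `y' = 0.9688 y + 0.0460 z`, `z' = -0.0485 y + 0.9189 z`; below it
#' `y' = 0.9688 y + 0.0420 z`, `z' = -0.0485 y + 0.8390 z`.
#'
#' @param coords Numeric length-3 vector or an n x 3 matrix of MNI mm
#'   coordinates.
#' @return Coordinates in Talairach space, same shape as the input.
#' @examples
#' mni_to_tal(c(0, 0, 10)) # c(0, 0.46, 9.189)
#' @export
mni_to_tal <- function(coords) {
  vec <- is.null(dim(coords))
  m <- matrix(as.numeric(coords), ncol = 3, byrow = vec && length(coords) == 3)
  up <- m[, 3] >= 0
  out <- cbind(
    0.9900 * m[, 1],
    0.9688 * m[, 2] + ifelse(up, 0.0460, 0.0420) * m[, 3],
    -0.0485 * m[, 2] + ifelse(up, 0.9189, 0.8390) * m[, 3]
  )
  if (vec) as.numeric(out) else out
}

#' Study-specific smoothing kernel width
#'
#' Maps a study's sample size to the FWHM of its modelled-activation kernel
#' by linear interpolation: the smallest studies get the widest kernel
#' (default 9 mm) and the largest the narrowest (default 8.5 mm), clamped
#' outside the range. Larger samples localise their peaks more reliably, so
#' their foci are blurred less.
#'
#' @param n_subjects Study sample size(s).
#' @param fwhm_range Length-2 mm range `c(at n_min, at n_max)`.
#' @param n_range Length-2 sample-size range for the interpolation.
#' @return FWHM in mm (vectorised over `n_subjects`).
#' @export
fwhm_for_study <- function(n_subjects, fwhm_range = c(9, 8.5),
                           n_range = c(12, 100)) {
  if (n_range[1] >= n_range[2]) stopf("`n_range` must be increasing")
  t <- pmin(pmax((n_subjects - n_range[1]) / diff(n_range), 0), 1)
  fwhm_range[1] + t * diff(fwhm_range)
}

# per-focus kernel sigmas for a foci tibble (adds a `sigma` column)
foci_with_sigma <- function(studies, fwhm_range = c(9, 8.5),
                            n_range = c(12, 100)) {
  mutate(studies,
         sigma = fwhm_to_sigma(fwhm_for_study(.data$n_subjects, fwhm_range,
                                              n_range)))
}

# log(1 - p) accumulation of focus kernels over the mask voxels;
# foci: matrix n x 3, sigmas length n. Returns vector over mask voxels.
ale_log_surv <- function(foci, sigmas, mask_xyz, voxel_vol) {
  acc <- numeric(nrow(mask_xyz))
  for (k in seq_len(nrow(foci))) {
    d2 <- (mask_xyz[, 1] - foci[k, 1])^2 + (mask_xyz[, 2] - foci[k, 2])^2 +
      (mask_xyz[, 3] - foci[k, 3])^2
    pk <- pmin(voxel_vol / (2 * pi * sigmas[k]^2)^1.5 *
                 exp(-d2 / (2 * sigmas[k]^2)), 1)
    acc <- acc + log1p(-pmin(pk, 1 - 1e-15))
  }
  acc
}

#' Activation likelihood estimation map
#'
#' Treats every reported focus as an isotropic 3D Gaussian probability that
#' the true peak lies in each voxel (probability mass per voxel, i.e.
#' density times voxel volume, clipped at 1) and combines foci as a
#' probabilistic union: `ALE(v) = 1 - prod_k (1 - p_k(v))`. With
#' `pooling = "all_foci"` (the original algorithm, default) the product runs
#' over every focus of every study; with `pooling = "by_study"` foci are
#' first combined into per-study modelled-activation maps which are then
#' unioned.
#'
#' @param studies Foci tibble (`study_id`, `n_subjects`, `x`, `y`, `z`, and
#'   optionally `direction`, `space`). Coordinates must already be in
#'   Talairach space (apply [mni_to_tal()] to MNI studies first).
#' @param mask A `voxel_map` brain mask; ALE is computed at mask voxels.
#' @param pooling `"all_foci"` or `"by_study"`.
#' @param fwhm_range,n_range Passed to [fwhm_for_study()].
#' @return A `voxel_map` of ALE values in \[0, 1\] (0 outside the mask).
#' @export
ale_map <- function(studies, mask, pooling = c("all_foci", "by_study"),
                    fwhm_range = c(9, 8.5), n_range = c(12, 100)) {
  pooling <- match.arg(pooling)
  if (nrow(studies) == 0L) stopf("no studies / foci supplied")
  studies <- foci_with_sigma(studies, fwhm_range, n_range)
  idx <- which(mask$mask)
  mask_xyz <- voxel_coords(mask, idx)
  vv <- mask$spacing^3
  foci <- as.matrix(studies[, c("x", "y", "z")])
  vals <- if (pooling == "all_foci") {
    1 - exp(ale_log_surv(foci, studies$sigma, mask_xyz, vv))
  } else {
    acc <- numeric(length(idx))
    for (sid in unique(studies$study_id)) {
      sel <- studies$study_id == sid
      ma <- 1 - exp(ale_log_surv(foci[sel, , drop = FALSE],
                                 studies$sigma[sel], mask_xyz, vv))
      acc <- acc + log1p(-pmin(ma, 1 - 1e-15))
    }
    1 - exp(acc)
  }
  out <- array(0, dim(mask$data))
  out[idx] <- vals
  voxel_map(out, mask$origin, mask$spacing, mask$mask)
}

#' Random-foci permutation null for ALE
#'
#' Builds the empirical null distribution of ALE values under spatial
#' randomness: in each permutation the same number of foci (with the same
#' per-focus kernel widths) is placed uniformly at random on mask voxel
#' centres, with no assumption about their distribution or separation, the
#' ALE map is recomputed, and all mask-voxel values are pooled into one
#' null sample.
#'
#' @param n_foci Number of foci per permutation.
#' @param per_focus_fwhm Vector of kernel FWHMs (mm), recycled to `n_foci`.
#' @param mask A `voxel_map` brain mask.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return Object of class `ale_null` holding the sorted pooled null sample.
#' @export
permutation_null <- function(n_foci, per_focus_fwhm, mask, n_perm = 5000,
                             seed = 1L) {
  if (n_perm < 1) stopf("`n_perm` must be >= 1")
  if (n_foci < 1) stopf("`n_foci` must be >= 1")
  idx <- which(mask$mask)
  if (length(idx) == 0L) stopf("brain mask is empty")
  sigmas <- rep_len(fwhm_to_sigma(per_focus_fwhm), n_foci)
  mask_xyz <- voxel_coords(mask, idx)
  vv <- mask$spacing^3
  sample_list <- vector("list", n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      foci <- mask_xyz[sample.int(length(idx), n_foci, replace = TRUE), ,
                       drop = FALSE]
      sample_list[[p]] <- 1 - exp(ale_log_surv(foci, sigmas, mask_xyz, vv))
    }
  })
  structure(
    list(values = sort(unlist(sample_list)), n_perm = n_perm,
         n_foci = n_foci, seed = seed),
    class = "ale_null")
}

#' @export
print.ale_null <- function(x, ...) {
  cat(sprintf("<ale_null> %d permutations x %d foci; %d pooled values\n",
              x$n_perm, x$n_foci, length(x$values)))
  invisible(x)
}

#' Voxelwise empirical p-values against an ALE null
#'
#' `p(v) = (#\{null >= ALE(v)\} + 1) / (N + 1)`: the add-one continuity
#' correction keeps p strictly positive (an observed value above the whole
#' null sample gets `1/(N+1)`) and an observed ALE of 0 gets p = 1.
#'
#' @param ale A `voxel_map` of observed ALE values.
#' @param null An `ale_null`.
#' @return A `voxel_map` of p-values over the mask (1 outside).
#' @export
ale_p_map <- function(ale, null) {
  idx <- which(ale$mask)
  obs <- ale$data[idx]
  nn <- length(null$values)
  cnt_lt <- findInterval(obs, null$values, left.open = TRUE)
  p <- (nn - cnt_lt + 1) / (nn + 1)
  out <- array(1, dim(ale$data))
  out[idx] <- p
  voxel_map(out, ale$origin, ale$spacing, ale$mask)
}

#' Benjamini-Hochberg FDR threshold
#'
#' Step-up procedure with the independence constant: with sorted p-values
#' `p(1) <= ... <= p(m)`, the cut-off is the largest `p(i)` satisfying
#' `p(i) <= i * q / m`; every p-value at or below the cut-off is rejected.
#' Returns 0 when nothing can be rejected.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q Target false discovery rate (default 0.05).
#' @return The p-value cut-off (0 if no rejections).
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stopf("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L) 0 else ps[max(ok)]
}

#' Extract supra-threshold result clusters
#'
#' Finds 26-connected components of significant voxels, drops components
#' smaller than the minimum extent (voxel count times voxel volume, with the
#' boundary case of exact equality retained), and reports each survivor's
#' volume, peak ALE value and peak coordinate.
#'
#' @param sig Logical 3D array (or `voxel_map` with 0/1 data) of significant
#'   voxels.
#' @param ale The ALE `voxel_map` on the same grid.
#' @param min_volume_mm3 Minimum cluster extent in mm^3 (default 224).
#' @return Tibble with columns `volume_mm3`, `x`, `y`, `z`, `peak_ale`,
#'   sorted by decreasing volume then decreasing peak.
#' @export
cluster_extract <- function(sig, ale, min_volume_mm3 = 224) {
  fg <- if (inherits(sig, "voxel_map")) sig$data > 0 & sig$mask else sig
  if (!identical(dim(fg), dim(ale$data))) stopf("maps are on different grids")
  labels <- connected_components_26(fg)
  vv <- ale$spacing^3
  out <- list()
  for (lab in setdiff(unique(as.integer(labels)), 0L)) {
    idx <- which(labels == lab)
    vol <- length(idx) * vv
    if (vol < min_volume_mm3) next
    peak <- idx[which.max(ale$data[idx])]
    xyz <- voxel_coords(ale, peak)
    out[[length(out) + 1L]] <- tibble(
      volume_mm3 = vol, x = xyz[1], y = xyz[2], z = xyz[3],
      peak_ale = ale$data[peak])
  }
  if (length(out) == 0L)
    return(tibble(volume_mm3 = numeric(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), peak_ale = numeric(0)))
  bind_rows(out) |> arrange(desc(.data$volume_mm3), desc(.data$peak_ale))
}

#' Coordinate-based meta-analysis of study foci
#'
#' Full ALE analysis for one contrast direction: modelled-activation union
#' map, random-foci permutation null with the same foci count and kernel
#' widths, voxelwise empirical p-values, FDR thresholding and extraction of
#' result clusters above the minimum extent.
#'
#' @param studies Foci tibble (Talairach space; rows with other `direction`
#'   values should be filtered out by the caller).
#' @param mask A `voxel_map` brain mask.
#' @param n_perm Number of random-foci permutations (default 5000).
#' @param q FDR level (default 0.05).
#' @param min_volume_mm3 Minimum cluster extent (default 224).
#' @param seed Integer seed for the permutation null.
#' @param pooling,fwhm_range,n_range Passed to [ale_map()].
#' @return Object of class `ale_result` with elements `ale` (voxel_map),
#'   `p` (voxel_map), `clusters` (tibble), `fdr_cutoff`, `null`, plus the
#'   parameters used.
#' @export
ale_meta <- function(studies, mask, n_perm = 5000, q = 0.05,
                     min_volume_mm3 = 224, seed = 1L,
                     pooling = "all_foci", fwhm_range = c(9, 8.5),
                     n_range = c(12, 100)) {
  studies <- foci_with_sigma(studies, fwhm_range, n_range)
  ale <- ale_map(studies, mask, pooling = pooling, fwhm_range = fwhm_range,
                 n_range = n_range)
  null <- permutation_null(nrow(studies), sigma_to_fwhm(studies$sigma), mask,
                           n_perm = n_perm, seed = seed)
  p <- ale_p_map(ale, null)
  cutoff <- fdr_threshold(p$data[p$mask], q = q)
  sig <- array(FALSE, dim(p$data))
  sig[p$mask] <- p$data[p$mask] <= cutoff & ale$data[p$mask] > 0
  clusters <- cluster_extract(sig, ale, min_volume_mm3 = min_volume_mm3)
  structure(
    list(ale = ale, p = p, clusters = clusters, fdr_cutoff = cutoff,
         sig = sig, null = null, q = q, n_perm = n_perm,
         min_volume_mm3 = min_volume_mm3, seed = seed),
    class = "ale_result")
}

sigma_to_fwhm <- function(sigma) sigma * sqrt(8 * log(2))

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf(
    "<ale_result> %d result cluster(s); FDR cutoff p <= %.3g (q = %g)\n",
    nrow(x$clusters), x$fdr_cutoff, x$q))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @export
tidy.ale_result <- function(x, ...) x$clusters

#' @export
glance.ale_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         max_ale = max(x$ale$data),
         fdr_cutoff = x$fdr_cutoff,
         sig_voxel_fraction = mean(x$p$data[x$p$mask] <= x$fdr_cutoff),
         n_perm = x$n_perm, q = x$q)
}

#' @export
autoplot.ale_result <- function(object, z = 0, ...) {
  autoplot(object$ale, z = z) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(fill = "ALE")
}
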