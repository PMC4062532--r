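#' Euclidean distance between two foci
#'
#' @param a,b Numeric length-3 mm coordinates.
#' @return Distance in mm.
#' @export
focus_distance <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

#' Empirical random voxel-pair distance null
#'
#' Distances between randomly chosen brain locations provide the reference
#' for judging whether a gene-expression peak and an MRI result cluster are
#' unusually close. Draws `n_pairs` ordered pairs of voxel centres uniformly
#' with replacement from the mask and records their Euclidean distances.
#'
#' @param mask A `voxel_map` brain mask with at least 2 voxels.
#' @param n_pairs Number of pairs (default 200000).
#' @param seed Integer seed.
#' @return Object of class `distance_null` holding the sampled distances.
#' @export
sample_null <- function(mask, n_pairs = 200000, seed = 1L) {
  idx <- which(mask$mask)
  if (length(idx) < 2L) stopf("mask must contain at least 2 voxels")
  with_seed(seed, {
    a <- voxel_coords(mask, sample(idx, n_pairs, replace = TRUE))
    b <- voxel_coords(mask, sample(idx, n_pairs, replace = TRUE))
  })
  structure(
    list(distances = sqrt(rowSums((a - b)^2)), n_pairs = n_pairs,
         seed = seed, mask_dim = dim(mask$data), spacing = mask$spacing),
    class = "distance_null")
}

#' @export
print.distance_null <- function(x, ...) {
  cat(sprintf("<distance_null> %d voxel pairs; distances %.1f-%.1f mm\n",
              x$n_pairs, min(x$distances), max(x$distances)))
  invisible(x)
}

#' Lower-tail distance cut points for given alpha levels
#'
#' The cut point for level `alpha` is the `ceiling(alpha * n)`-th order
#' statistic of the sampled pair distances: being closer than this occurs
#' with probability at most `alpha` for two random brain locations.
#'
#' @param null A [sample_null()] result.
#' @param alphas Levels in (0, 1), default `c(0.05, 0.01, 0.005)`.
#' @return Named numeric vector of cut points in mm.
#' @export
alpha_cutpoints <- function(null, alphas = c(0.05, 0.01, 0.005)) {
  d <- sort(null$distances)
  if (length(d) == 0L) stopf("empty distance sample")
  if (any(alphas <= 0 | alphas >= 1)) stopf("alphas must lie in (0, 1)")
  setNames(d[ceiling(alphas * length(d))], as.character(alphas))
}

#' @export
tidy.distance_null <- function(x, alphas = c(0.05, 0.01, 0.005), ...) {
  cp <- alpha_cutpoints(x, alphas)
  tibble(alpha = alphas, cutpoint_mm = unname(cp))
}

#' @export
glance.distance_null <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, mean_mm = mean(x$distances),
         max_mm = max(x$distances))
}

#' @export
autoplot.distance_null <- function(object, alphas = c(0.05, 0.01, 0.005),
                                   ...) {
  cp <- tidy(object, alphas)
  ggplot2::ggplot(tibble(d = object$distances), ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(data = cp,
                        ggplot2::aes(xintercept = .data$cutpoint_mm),
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "pair distance (mm)", y = "count")
}

#' Anatomical proximity table between expression peaks and MRI clusters
#'
#' Computes all cross pair distances between gene-expression extrema and MRI
#' result-cluster peaks, keeps those at or below the alpha = 0.05 cut point,
#' and annotates each with the most stringent significance level its
#' distance satisfies.
#'
#' @param expression_peaks Tibble with columns `x`, `y`, `z` and a `cluster`
#'   label (e.g. bound rows of [extract_extrema()] output per cluster).
#' @param mri_clusters Tibble with columns `x`, `y`, `z` and a `label`
#'   column identifying the MRI result cluster.
#' @param cutpoints Named cut-point vector from [alpha_cutpoints()], names
#'   parsing to the alpha levels.
#' @return Tibble `mri_label`, `cluster`, `distance_mm`, `level`, sorted by
#'   distance.
#' @export
overlap_table <- function(expression_peaks, mri_clusters, cutpoints) {
  alphas <- as.numeric(names(cutpoints))
  ord <- order(alphas)                 # most stringent (smallest) first
  alphas <- alphas[ord]
  cutpoints <- cutpoints[ord]
  out <- list()
  for (i in seq_len(nrow(mri_clusters))) {
    for (j in seq_len(nrow(expression_peaks))) {
      dmm <- focus_distance(
        c(mri_clusters$x[i], mri_clusters$y[i], mri_clusters$z[i]),
        c(expression_peaks$x[j], expression_peaks$y[j],
          expression_peaks$z[j]))
      sat <- which(dmm <= cutpoints)
      if (length(sat) == 0L) next
      out[[length(out) + 1L]] <- tibble(
        mri_label = mri_clusters$label[i],
        cluster = expression_peaks$cluster[j],
        distance_mm = dmm,
        level = alphas[min(sat)])
    }
  }
  if (length(out) == 0L)
    return(tibble(mri_label = character(0), cluster = character(0),
                  distance_mm = numeric(0), level = numeric(0)))
  bind_rows(out) |> arrange(.data$distance_mm)
}
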