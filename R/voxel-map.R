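#' Scalar fields on a regular stereotactic voxel grid
#'
#' A `voxel_map` holds a scalar value per voxel of a regular 3D grid in
#' stereotactic millimetre space (right-anterior-superior positive), together
#' with a binary brain mask on the same grid. It is the common currency
#' between the expression-mapping and meta-analysis stages: cluster mean-Z
#' maps, ALE maps, p-value maps and masks are all `voxel_map` objects.
#'
#' Voxel `(i, j, k)` (1-based array indices) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing`; `origin` is therefore the centre of
#' the first voxel, and extents are half-open in the usual imaging sense.
#'
#' @param data Numeric 3D array of voxel values.
#' @param origin Numeric length-3: mm coordinate of the centre of voxel
#'   `(1, 1, 1)`.
#' @param spacing Isotropic voxel edge length in mm (> 0).
#' @param mask Logical 3D array with the same dimensions as `data`, or `NULL`
#'   for an all-`TRUE` mask.
#' @return An object of class `voxel_map`.
#' @export
voxel_map <- function(data, origin, spacing, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array")
  assert_scalar_num(spacing, "spacing", lower = 1e-9)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stopf("`origin` must be 3 finite mm coordinates")
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  if (!identical(dim(mask), dim(data)))
    stopf("`mask` and `data` dimensions differ")
  structure(
    list(data = data, mask = mask, origin = as.numeric(origin),
         spacing = as.numeric(spacing)),
    class = "voxel_map"
  )
}

#' @export
print.voxel_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_map> %d x %d x %d voxels at %g mm (%d in mask)\n  value range: [%g, %g]\n",
    d[1], d[2], d[3], x$spacing, sum(x$mask),
    min(x$data[x$mask]), max(x$data[x$mask])))
  invisible(x)
}

# voxel-centre coordinates for all voxels (rows) or a subset of linear indices
voxel_coords <- function(vm, idx = NULL) {
  d <- dim(vm$data)
  if (is.null(idx)) idx <- seq_len(prod(d))
  ijk <- arrayInd(idx, d)
  sweep((ijk - 1) * vm$spacing, 2, vm$origin, `+`)
}

# linear index of the voxel whose centre is nearest to each mm coordinate
# (rows of xyz); coordinates are clamped onto the grid
coords_to_index <- function(vm, xyz) {
  d <- dim(vm$data)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  ijk <- round(sweep(xyz, 2, vm$origin, `-`) / vm$spacing) + 1
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), d[a])
  as.integer(ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1))
}

#' Ellipsoidal brain mask on a voxel grid
#'
#' Builds a binary mask of all voxels whose centres lie inside the ellipsoid
#' `(x/a)^2 + (y/b)^2 + (z/c)^2 <= 1` centred at the stereotactic origin. The
#' grid is symmetric about the origin on each axis and covers the ellipsoid
#' exactly. The default semi-axes (68, 86, 59 mm) give a Talairach-like
#' whole-brain extent and serve as the voxel universe for the random
#' voxel-pair distance null and for random-foci ALE permutations.
#'
#' @param voxel_size_mm Voxel edge length in mm (> 0).
#' @param semi_axes_mm Numeric length-3 ellipsoid semi-axes (x, y, z) in mm.
#' @return A `voxel_map` whose `data` is 1 inside / 0 outside and whose
#'   `mask` is the corresponding logical array.
#' @examples
#' m <- gen_brain_mask(4)
#' sum(m$mask) * 4^3 / (4 / 3 * pi * prod(c(68, 86, 59))) # ~ 1
#' @export
gen_brain_mask <- function(voxel_size_mm = 2, semi_axes_mm = c(68, 86, 59)) {
  assert_scalar_num(voxel_size_mm, "voxel_size_mm", lower = 1e-9)
  if (length(semi_axes_mm) != 3L || any(semi_axes_mm <= 0))
    stopf("`semi_axes_mm` must be 3 positive lengths")
  centers <- lapply(semi_axes_mm, function(a) {
    n <- ceiling(2 * a / voxel_size_mm)
    (seq_len(n) - (n + 1) / 2) * voxel_size_mm
  })
  r2 <- outer(
    outer((centers[[1]] / semi_axes_mm[1])^2,
          (centers[[2]] / semi_axes_mm[2])^2, `+`),
    (centers[[3]] / semi_axes_mm[3])^2, `+`)
  mask <- r2 <= 1
  origin <- vapply(centers, `[`, numeric(1), 1L)
  voxel_map(data = array(as.numeric(mask), dim(mask)), origin = origin,
            spacing = voxel_size_mm, mask = mask)
}

#' @describeIn voxel_map One row per voxel inside the mask, with voxel-centre
#'   coordinates in mm and the voxel value.
#' @param x A `voxel_map`.
#' @param ... Unused.
#' @export
tidy.voxel_map <- function(x, ...) {
  idx <- which(x$mask)
  xyz <- voxel_coords(x, idx)
  tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], value = x$data[idx])
}

#' @export
autoplot.voxel_map <- function(object, z = 0, ...) {
  df <- tidy(object)
  zs <- sort(unique(df$z))
  zsel <- zs[which.min(abs(zs - z))]
  ggplot2::ggplot(dplyr::filter(df, .data$z == zsel),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(title = sprintf("axial slice z = %g mm", zsel),
                  x = "x (mm)", y = "y (mm)", fill = "value")
}

# Add value * exp(-d^2 / (2 sigma^2)) around each point to a field on vm's
# grid. Used for cluster mean-Z maps: the kernel has unit peak so an isolated
# region keeps its Z value at its own voxel.
splat_gaussian <- function(vm, xyz, values, sigma) {
  field <- array(0, dim(vm$data))
  grid_xyz <- voxel_coords(vm)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  for (r in seq_len(nrow(xyz))) {
    if (values[r] == 0) next
    d2 <- (grid_xyz[, 1] - xyz[r, 1])^2 + (grid_xyz[, 2] - xyz[r, 2])^2 +
      (grid_xyz[, 3] - xyz[r, 3])^2
    field <- field + array(values[r] * exp(-d2 / (2 * sigma^2)), dim(vm$data))
  }
  voxel_map(field, vm$origin, vm$spacing, vm$mask)
}

# 26-connected components of a logical 3D array; returns an integer label
# array (0 = background). Plain BFS over the foreground voxels.
connected_components_26 <- function(fg) {
  d <- dim(fg)
  labels <- array(0L, d)
  idx_fg <- which(fg)
  if (length(idx_fg) == 0L) return(labels)
  nbr <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  cur <- 0L
  for (seed_idx in idx_fg) {
    if (labels[seed_idx] != 0L) next
    cur <- cur + 1L
    queue <- seed_idx
    labels[seed_idx] <- cur
    while (length(queue)) {
      ijk <- arrayInd(queue, d)
      cand <- do.call(rbind, lapply(seq_len(nrow(nbr)), function(r)
        sweep(ijk, 2, as.integer(nbr[r, ]), `+`)))
      keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[keep, , drop = FALSE]
      lin <- unique(cand[, 1] + d[1] * (cand[, 2] - 1) +
                      d[1] * d[2] * (cand[, 3] - 1))
      lin <- lin[fg[lin] & labels[lin] == 0L]
      labels[lin] <- cur
      queue <- lin
    }
  }
  labels
}
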