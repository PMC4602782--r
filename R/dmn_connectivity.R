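#' DMN seed specification
#'
#' A named sphere in MNI mm. The canonical three-seed DMN set places seeds in
#' the medial prefrontal cortex (-1, 47, -4), posterior cingulate cortex
#' (-5, -49, 40) and left lateral parietal cortex (-45, -67, 36); the radius
#' defaults to 6 mm, with radius 0 meaning the single voxel containing the
#' centre.
#'
#' @param name seed name.
#' @param center_mni_mm length-3 mm coordinates.
#' @param radius_mm sphere radius in mm (>= 0).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(name, center_mni_mm, radius_mm = 6) {
  dmn_assert(length(center_mni_mm) == 3 && radius_mm >= 0, "bad_seed",
             "seed needs 3 mm coordinates and a non-negative radius")
  structure(list(name = name, center_mni_mm = as.numeric(center_mni_mm),
                 radius_mm = radius_mm), class = "seed_spec")
}

#' @rdname seed_spec
#' @export
default_dmn_seeds <- function(radius_mm = 6) {
  list(seed_spec("MPFC", c(-1, 47, -4), radius_mm),
       seed_spec("PCC", c(-5, -49, 40), radius_mm),
       seed_spec("LP", c(-45, -67, 36), radius_mm))
}

#' Mean time series of a seed sphere
#'
#' Averages the time series of every voxel whose centre lies within
#' `radius_mm` (Euclidean, in mm) of the seed centre. Radius 0 selects the
#' voxel containing the centre.
#'
#' @param bold a [bold_series()].
#' @param seed a [seed_spec()].
#' @return Numeric vector, one value per volume.
#' @export
seed_timeseries <- function(bold, seed) {
  sh <- dim(bold$data)[1:3]
  if (seed$radius_mm <= 0) {
    vox <- round(mm_to_vox(bold$affine, seed$center_mni_mm))
    dmn_assert(all(vox >= 1) && all(vox <= sh), "empty_seed",
               sprintf("seed '%s' centre falls outside the grid", seed$name))
    return(as.numeric(bold$data[vox[1], vox[2], vox[3], ]))
  }
  sel <- sphere_voxels(sh, bold$affine, seed$center_mni_mm, seed$radius_mm)
  dmn_assert(any(sel), "empty_seed",
             sprintf("seed '%s' sphere contains no voxels", seed$name))
  d <- dim(bold$data)
  M <- matrix(bold$data, prod(sh), d[4])
  colMeans(M[sel, , drop = FALSE])
}

#' Voxelwise seed correlation map
#'
#' Pearson correlation at lag zero between the seed time series and every
#' voxel's time series (both demeaned internally). Voxels with zero temporal
#' variance are marked missing (`NA`).
#'
#' @param bold a [bold_series()].
#' @param seed_ts numeric seed time series, one value per volume.
#' @return A [volume_map()] of kind `"r"`.
#' @export
correlation_map <- function(bold, seed_ts) {
  d <- dim(bold$data)
  dmn_assert(length(seed_ts) == d[4], "bad_params",
             "seed series length must equal the volume count")
  yc <- seed_ts - mean(seed_ts)
  sy <- sqrt(sum(yc^2))
  dmn_assert(sy > 0, "constant_seed", "seed time series is constant")
  Y <- matrix(bold$data, prod(d[1:3]), d[4])
  Yc <- Y - rowMeans(Y)
  num <- Yc %*% yc
  den <- sqrt(rowSums(Yc^2)) * sy
  r <- as.numeric(num) / den
  r[den == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  volume_map(array(r, dim = d[1:3]), bold$affine, kind = "r")
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r) = 0.5 log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform for correlation coefficients. Values with `|r| = 1` become
#' missing with a warning.
#'
#' @param map a [volume_map()] of kind `"r"`.
#' @return A [volume_map()] of kind `"z"`.
#' @export
fisher_z <- function(map) {
  dmn_assert(inherits(map, "volume_map") && map$kind == "r", "bad_map",
             "fisher_z expects a kind='r' map")
  r <- map$data
  sat <- is.finite(r) & abs(r) >= 1
  if (any(sat)) {
    warning(sprintf("fisher_z: %d voxel(s) with |r| = 1 set to NA", sum(sat)))
    r[sat] <- NA_real_
  }
  volume_map(atanh(r), map$affine, kind = "z")
}

#' Average several z maps voxelwise
#'
#' Arithmetic mean across maps on an identical grid; a voxel missing in any
#' contributor is missing in the result.
#'
#' @param z_maps list of [volume_map()] objects of kind `"z"`.
#' @return A [volume_map()] of kind `"z"`.
#' @export
mean_seed_zmap <- function(z_maps) {
  dmn_assert(length(z_maps) >= 1, "bad_params", "need at least one map")
  ref <- z_maps[[1]]
  for (m in z_maps)
    dmn_assert(same_grid(m, ref), "grid_mismatch",
               "z maps are not on the same grid")
  acc <- Reduce(`+`, lapply(z_maps, `[[`, "data"))
  volume_map(acc / length(z_maps), ref$affine, kind = "z")
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up rule: sort the p values ascending, find the largest rank `i` with
#' `p_(i) <= i q / m`, and select every test with `p <= p_(i)`; selects
#' nothing if no rank qualifies.
#'
#' @param p_values numeric vector of p values in `[0, 1]` (NA allowed; never
#'   selected).
#' @param q target false discovery rate, in (0, 1).
#' @return Logical vector, `TRUE` for selected (significant) tests.
#' @export
fdr_select <- function(p_values, q) {
  dmn_assert(q > 0 && q < 1, "bad_params", "q must lie in (0, 1)")
  ok <- !is.na(p_values)
  dmn_assert(all(p_values[ok] >= 0 & p_values[ok] <= 1), "bad_params",
             "p values must lie in [0, 1]")
  out <- logical(length(p_values))
  p <- p_values[ok]
  m <- length(p)
  if (m == 0) return(out)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= seq_len(m) * q / m)
  if (length(pass) > 0) out[ok] <- p <= ps[max(pass)]
  out
}

#' Group-level per-seed significance mask
#'
#' For one seed, runs a voxelwise one-sample t test of the subjects' z values
#' against zero (two-sided), then applies Benjamini-Hochberg FDR selection at
#' rate `q` across the tested voxels. Voxels missing in any subject are
#' excluded from testing. With `direction = "positive"` (the default) only
#' significantly *positive* connectivity enters the mask: network membership
#' means correlated activity, and after global-signal regression much of the
#' brain acquires a small consistently negative correlation with any seed
#' that a two-sided membership rule would wrongly admit.
#'
#' @param z_maps list of subject [volume_map()]s (kind `"z"`) for one seed;
#'   at least 3 subjects.
#' @param q FDR rate.
#' @param direction `"positive"` to keep only voxels with positive mean z,
#'   `"both"` to keep any significant voxel.
#' @return A [binary_mask()] of surviving voxels.
#' @export
seed_significance_mask <- function(z_maps, q = 0.05,
                                   direction = c("positive", "both")) {
  direction <- match.arg(direction)
  n <- length(z_maps)
  dmn_assert(n >= 3, "too_few_subjects",
             "seed significance mask needs at least 3 subjects")
  ref <- z_maps[[1]]
  Z <- vapply(z_maps, function(m) as.vector(m$data),
              numeric(length(ref$data)))
  Z <- matrix(Z, nrow = length(ref$data))
  complete <- rowSums(is.na(Z)) == 0
  mu <- rowMeans(Z)
  sd <- sqrt(pmax(rowSums((Z - mu)^2) / (n - 1), 0))
  tt <- ifelse(sd > 0, mu / (sd / sqrt(n)), 0)
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  p[!complete] <- NA_real_
  sel <- fdr_select(p, q)
  if (direction == "positive") sel <- sel & mu > 0
  binary_mask(array(sel, dim = dim(ref$data)), ref$affine)
}

#' Two-of-three conjunction mask
#'
#' A voxel belongs to the conjunction DMN mask when it is significant for at
#' least 2 of the 3 per-seed masks.
#'
#' @param masks list of exactly 3 [binary_mask()]s on one grid.
#' @return A [binary_mask()].
#' @export
conjunction <- function(masks) {
  dmn_assert(length(masks) == 3, "bad_params", "conjunction expects 3 masks")
  ref <- masks[[1]]
  for (m in masks)
    dmn_assert(same_grid(m, ref), "grid_mismatch",
               "conjunction masks are not on the same grid")
  votes <- Reduce(`+`, lapply(masks, function(m) m$data * 1L))
  binary_mask(votes >= 2, ref$affine)
}

#' Per-subject seed z maps and group conjunction mask
#'
#' Convenience wrapper over the seed-level operations: computes, for every
#' subject, the three seed correlation maps and their Fisher z transforms,
#' averages them into the subject's DMN map, and derives the conjunction mask
#' from the group-level per-seed significance masks of the reference
#' subjects (by default the healthy controls, so patient data never shapes
#' the mask).
#'
#' @param processed_bolds list of preprocessed [bold_series()].
#' @param seeds list of 3 [seed_spec()]s.
#' @param reference logical vector: which subjects define the significance
#'   masks (default all).
#' @param q FDR rate for the per-seed masks.
#' @return A list with `mean_z_maps` (per subject), `seed_z_maps` (list of 3
#'   lists), `seed_masks` (3 [binary_mask()]s) and `dmn_mask`.
#' @export
dmn_conjunction_analysis <- function(processed_bolds, seeds,
                                     reference = rep(TRUE, length(processed_bolds)),
                                     q = 0.05) {
  dmn_assert(length(seeds) == 3, "bad_params", "expected exactly 3 seeds")
  seed_z <- lapply(seeds, function(sd) {
    lapply(processed_bolds, function(b)
      fisher_z(correlation_map(b, seed_timeseries(b, sd))))
  })
  mean_z <- lapply(seq_along(processed_bolds), function(i)
    mean_seed_zmap(lapply(seed_z, `[[`, i)))
  seed_masks <- lapply(seed_z, function(zl)
    seed_significance_mask(zl[reference], q))
  list(mean_z_maps = mean_z, seed_z_maps = seed_z,
       seed_masks = seed_masks, dmn_mask = conjunction(seed_masks))
}
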