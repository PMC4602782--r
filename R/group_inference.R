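#' Design information for group comparisons
#'
#' Group labels and nuisance covariates for the voxelwise models. Group is
#' coded by treatment contrasts with healthy controls as the reference, so a
#' negative patient coefficient reads as reduced connectivity relative to
#' controls; gender is a single 0/1 indicator (M = 0, F = 1).
#'
#' @param group character vector of `"HC"`, `"nonHE"`, `"MHE"` per subject.
#' @param age_years numeric vector.
#' @param gender character (`"M"`/`"F"`) or 0/1 numeric vector.
#' @return An object of class `design_info`.
#' @export
design_info <- function(group, age_years, gender) {
  n <- length(group)
  dmn_assert(length(age_years) == n && length(gender) == n, "bad_design",
             "group, age and gender must have equal length")
  dmn_assert(!anyNA(age_years) && !anyNA(gender), "bad_design",
             "every subject needs complete covariates")
  g01 <- if (is.numeric(gender)) gender else as.numeric(gender == "F")
  structure(list(group = as.character(group), age_years = as.numeric(age_years),
                 gender01 = g01), class = "design_info")
}

maps_to_matrix <- function(maps) {
  ref <- maps[[1]]
  for (m in maps)
    dmn_assert(same_grid(m, ref), "grid_mismatch",
               "subject maps are not on one grid")
  matrix(vapply(maps, function(m) as.vector(m$data),
                numeric(length(ref$data))),
         nrow = length(ref$data))
}

# residual maker: Y (v x n) regressed on X (n x p); returns list(rss, resid)
# age/gender columns for the voxelwise designs; a covariate with no
# variance in the analyzed subjects (e.g. a single-sex cohort) is dropped —
# adjusting for a constant is a no-op and would only make the design
# singular
covariate_columns <- function(design, sel = rep(TRUE, length(design$group))) {
  covars <- cbind(age_years = design$age_years[sel],
                  gender = design$gender01[sel])
  covars[, apply(covars, 2, stats::sd) > 0, drop = FALSE]
}

rss_under <- function(Ymat, X) {
  qx <- qr(X)
  dmn_assert(qx$rank == ncol(X), "collinear_design",
             "rank-deficient design in voxelwise model")
  Q <- qr.Q(qx)
  E <- Ymat - (Ymat %*% Q) %*% t(Q)   # rows = voxels
  list(rss = rowSums(E^2), resid = E)
}

#' Voxelwise covariate-adjusted one-way ANOVA
#'
#' At every masked voxel, tests the group factor in the linear model
#' `z ~ group + age + gender` by comparing the residual sum of squares of
#' the full model (intercept, group indicators with HC as reference, age,
#' gender) with the covariate-only reduced model. With the full three
#' groups F has (2, n - 5) degrees of freedom; a two-group design reduces
#' to F(1, n - 4), the square of the corresponding post hoc t. A covariate
#' that is constant across the analyzed subjects is dropped. Voxels outside
#' the mask, or missing for any subject, are `NA`.
#'
#' @param subject_maps list of per-subject [volume_map()]s (the mean DMN z
#'   maps), all groups together.
#' @param design a [design_info()] with >= 2 subjects in each of 3 groups.
#' @param mask [binary_mask()] of voxels to test.
#' @return A list with `f_map`, `p_map` ([volume_map()]s) and `residual_maps`
#'   (per-subject full-model residual [volume_map()]s, for smoothness
#'   estimation).
#' @export
voxelwise_anova <- function(subject_maps, design, mask) {
  lev <- intersect(c("HC", "nonHE", "MHE"), unique(design$group))
  dmn_assert(length(lev) >= 2, "bad_design", "need at least 2 groups")
  tab <- table(factor(design$group, levels = lev))
  dmn_assert(all(tab >= 2), "bad_design",
             "each group needs at least 2 subjects")
  n <- length(subject_maps)
  dmn_assert(n == length(design$group), "bad_design",
             "maps and design describe different subject counts")
  Y <- maps_to_matrix(subject_maps)
  keep <- as.vector(mask$data) & rowSums(is.na(Y)) == 0
  Ym <- Y[keep, , drop = FALSE]
  g <- factor(design$group, levels = lev)
  ind <- vapply(lev[-1], function(l) as.numeric(g == l), numeric(n))
  covars <- covariate_columns(design)
  Xfull <- cbind(1, ind, covars)
  storage.mode(Xfull) <- "double"
  df1 <- length(lev) - 1
  Xred <- Xfull[, c(1, seq_len(ncol(covars)) + 1 + df1), drop = FALSE]
  full <- rss_under(Ym, Xfull)
  red <- rss_under(Ym, Xred)
  df2 <- n - ncol(Xfull)
  dmn_assert(df2 >= 1, "bad_design", "too few subjects for the model")
  Fv <- ((red$rss - full$rss) / df1) / (full$rss / df2)
  # voxels fitted exactly (e.g. identical values): define F = 0
  scale <- rowSums(Ym^2) + 1e-300
  Fv[full$rss / scale <= 1e-24] <- 0
  Fv <- pmax(Fv, 0)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  shape <- dim(mask$data)
  fm <- array(NA_real_, shape); fm[keep] <- Fv
  pm <- array(NA_real_, shape); pm[keep] <- p
  resid_maps <- lapply(seq_len(n), function(i) {
    r <- array(NA_real_, shape); r[keep] <- full$resid[, i]
    volume_map(r, mask$affine, kind = "mean")
  })
  list(f_map = volume_map(fm, mask$affine, kind = "F"),
       p_map = volume_map(pm, mask$affine, kind = "p"),
       residual_maps = resid_maps, df = c(df1, df2))
}

#' Voxelwise post hoc two-group t test with covariates
#'
#' t statistic for the group-indicator coefficient in `z ~ group + age +
#' gender` restricted to two groups; two-sided p with n - 4 degrees of
#' freedom. The indicator is 1 for `group_b`, so t > 0 means `group_b` above
#' `group_a`.
#'
#' @param subject_maps list of [volume_map()]s covering the subjects in
#'   `design` (all groups may be present; the two contrasted groups are
#'   selected via `design`).
#' @param design a [design_info()] aligned with `subject_maps`.
#' @param group_a,group_b the two group labels to contrast.
#' @param mask [binary_mask()] of voxels to test.
#' @return A list with `t_map` and `p_map` [volume_map()]s.
#' @export
posthoc_t <- function(subject_maps, design, group_a, group_b, mask) {
  sel <- design$group %in% c(group_a, group_b)
  dmn_assert(sum(design$group == group_a) >= 2 &&
               sum(design$group == group_b) >= 2, "bad_design",
             "both groups need at least 2 subjects")
  Y <- maps_to_matrix(subject_maps)[, sel, drop = FALSE]
  ind <- as.numeric(design$group[sel] == group_b)
  X <- cbind(1, ind, covariate_columns(design, sel))
  qx <- qr(X)
  dmn_assert(qx$rank == ncol(X), "collinear_design",
             "rank-deficient design in post hoc model")
  keep <- as.vector(mask$data) & rowSums(is.na(Y)) == 0
  Ym <- Y[keep, , drop = FALSE]
  n <- nrow(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- Ym %*% X %*% XtXinv             # voxel x coef
  E <- Ym - B %*% t(X)
  df <- n - ncol(X)
  sigma2 <- rowSums(E^2) / df
  se <- sqrt(sigma2 * XtXinv[2, 2])
  exact_fit <- rowSums(E^2) / (rowSums(Ym^2) + 1e-300) <= 1e-24
  tt <- ifelse(se > 0 & !exact_fit, B[, 2] / se, 0)
  p <- 2 * stats::pt(-abs(tt), df)
  shape <- dim(mask$data)
  tm <- array(NA_real_, shape); tm[keep] <- tt
  pm <- array(NA_real_, shape); pm[keep] <- p
  list(t_map = volume_map(tm, mask$affine, kind = "t"),
       p_map = volume_map(pm, mask$affine, kind = "p"), df = df)
}

#' Estimate residual spatial smoothness
#'
#' Classical first-difference estimator: along each axis, the lag-one
#' spatial correlation of the standardized residual field is
#' `r1 = 1 - var(diff) / (2 var)`; assuming a Gaussian autocorrelation this
#' corresponds to `FWHM = d sqrt(-2 log 2 / log r1)` for voxel size d.
#' Estimates are averaged across residual maps and clipped below at the
#' voxel size (a spatially white field).
#'
#' @param residual_maps list of >= 2 residual [volume_map()]s.
#' @param mask [binary_mask()]; only voxel pairs fully inside are used.
#' @return Length-3 numeric, per-axis FWHM in mm.
#' @export
estimate_smoothness <- function(residual_maps, mask) {
  dmn_assert(length(residual_maps) >= 2, "bad_params",
             "need at least 2 residual maps")
  dmn_assert(any(mask$data), "empty_mask", "mask is empty")
  vs <- affine_voxel_size(mask$affine)
  shape <- dim(mask$data)
  r1 <- matrix(NA_real_, length(residual_maps), 3)
  for (m in seq_along(residual_maps)) {
    x <- residual_maps[[m]]$data
    x[!mask$data] <- NA
    v <- stats::var(as.vector(x), na.rm = TRUE)
    dmn_assert(is.finite(v) && v > 0, "degenerate_residuals",
               "residual map is constant inside the mask")
    for (a in 1:3) {
      n <- shape[a]
      if (n < 2) next
      idx1 <- slice_index(shape, a, 1:(n - 1))
      idx2 <- slice_index(shape, a, 2:n)
      d <- x[idx2] - x[idx1]
      vd <- stats::var(as.vector(d), na.rm = TRUE)
      if (is.finite(vd)) r1[m, a] <- 1 - vd / (2 * v)
    }
  }
  r1bar <- colMeans(r1, na.rm = TRUE)
  fwhm <- numeric(3)
  for (a in 1:3) {
    fwhm[a] <- if (!is.finite(r1bar[a]) || r1bar[a] <= 0) vs[a] else
      max(vs[a] * sqrt(-2 * log(2) / log(r1bar[a])), vs[a])
  }
  fwhm
}

# linear indices of the sub-array where axis `a` is restricted to `range`
slice_index <- function(shape, a, range) {
  idx <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
  idx[[a]] <- range
  arr <- array(seq_len(prod(shape)), shape)
  as.vector(arr[idx[[1]], idx[[2]], idx[[3]]])
}

#' Cluster-correction settings
#'
#' @param cluster_forming_p two-sided voxelwise threshold forming clusters.
#' @param alpha family-wise error rate for the corrected cluster extent.
#' @param n_iterations Monte-Carlo iterations (>= 100).
#' @param connectivity 6, 18 or 26-neighbour cluster connectivity.
#' @param smoothness_fwhm_mm per-axis FWHM of the null field (mm), usually
#'   from [estimate_smoothness()].
#' @return An object of class `cluster_correction`.
#' @export
cluster_correction <- function(cluster_forming_p = 0.01, alpha = 0.05,
                               n_iterations = 1000, connectivity = 26,
                               smoothness_fwhm_mm = c(8, 8, 8)) {
  dmn_assert(connectivity %in% c(6, 18, 26), "bad_params",
             "connectivity must be 6, 18 or 26")
  dmn_assert(n_iterations >= 100, "bad_params", "need >= 100 iterations")
  structure(list(cluster_forming_p = cluster_forming_p, alpha = alpha,
                 n_iterations = as.integer(n_iterations),
                 connectivity = as.integer(connectivity),
                 smoothness_fwhm_mm = rep_len(smoothness_fwhm_mm, 3),
                 min_extent_k = NA_integer_),
            class = "cluster_correction")
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  if (connectivity == 6) g[ord == 1, , drop = FALSE]
  else if (connectivity == 18) g[ord <= 2, , drop = FALSE]
  else g
}

# Connected components of a logical 3-D array. Returns an integer array of
# labels (0 = background), component ids in arbitrary order.
label_components <- function(bin, connectivity = 26) {
  shape <- dim(bin)
  offs <- neighbour_offsets(connectivity)
  storage.mode(offs) <- "integer"
  labels <- .label_components_cpp(as.logical(bin), as.integer(shape), offs)
  array(labels, shape)
}

#' Monte-Carlo minimum cluster extent (AlphaSim-style)
#'
#' Estimates the smallest cluster size k such that, under a smooth Gaussian
#' null field on the mask, the probability of observing any suprathreshold
#' cluster of size >= k is at most `alpha`. Each iteration draws white noise
#' on the grid, smooths it to the configured FWHM with the same separable
#' kernel as the pipeline, standardizes each voxel by its exact
#' kernel-induced standard deviation (so the voxelwise exceedance rate
#' equals the forming p everywhere, including lattice edges), thresholds
#' two-sided, and records the maximum cluster size inside the mask.
#'
#' @param correction a [cluster_correction()].
#' @param mask [binary_mask()] defining the search region.
#' @param rng_seed integer seed for the Monte-Carlo loop.
#' @return The [cluster_correction()] with `min_extent_k` filled in, plus a
#'   `max_null_sizes` attribute holding the per-iteration maxima.
#' @export
alphasim_min_extent <- function(correction, mask, rng_seed = 1L) {
  dmn_assert(any(mask$data), "empty_mask", "mask is empty")
  vs <- affine_voxel_size(mask$affine)
  dmn_assert(all(correction$smoothness_fwhm_mm >= vs - 1e-9), "bad_params",
             "smoothness FWHM below voxel size")
  shape <- dim(mask$data)
  ker <- lapply(1:3, function(a)
    gauss_smooth_matrix(shape[a],
                        fwhm_to_sigma(correction$smoothness_fwhm_mm[a]) / vs[a]))
  # exact per-voxel SD of the smoothed white field: separable sum of squares
  sd_axis <- lapply(ker, function(S) rowSums(S^2))
  sd_vox <- sqrt(outer(outer(sd_axis[[1]], sd_axis[[2]]), sd_axis[[3]]))
  zcrit <- stats::qnorm(1 - correction$cluster_forming_p / 2)
  inmask <- as.vector(mask$data)
  set.seed(as.integer(rng_seed))
  n_iter <- correction$n_iterations
  maxes <- integer(n_iter)
  n_vox <- prod(shape)
  chunk <- max(1L, min(n_iter, as.integer(2^22 %/% n_vox)))
  done <- 0L
  sdv <- as.vector(sd_vox)
  while (done < n_iter) {
    nb <- min(chunk, n_iter - done)
    w <- array(stats::rnorm(n_vox * nb), c(shape, nb))
    f <- smooth_separable(w, ker)
    dim(f) <- c(n_vox, nb)
    supra <- (abs(f) > zcrit * sdv) & inmask
    for (b in seq_len(nb)) {
      sb <- supra[, b]
      if (!any(sb)) { maxes[done + b] <- 0L; next }
      labs <- label_components(array(sb, shape), correction$connectivity)
      maxes[done + b] <- max(tabulate(labs[labs > 0L]))
    }
    done <- done + nb
  }
  # smallest k with P(max null cluster >= k) <= alpha
  kmax <- max(maxes, 0L)
  k <- 1L
  while (k <= kmax &&
         mean(maxes >= k) > correction$alpha) k <- k + 1L
  correction$min_extent_k <- k
  attr(correction, "max_null_sizes") <- maxes
  correction
}

#' Extract significant clusters from a statistic map
#'
#' Connected components of the suprathreshold set `{p < forming_p}` under
#' the configured connectivity; components smaller than `min_extent_k` are
#' dropped. Clusters are returned sorted by size (descending); each carries
#' its voxel index set, peak statistic (maximum `|stat|`) and the peak's MNI
#' coordinates.
#'
#' @param stat_map statistic [volume_map()] (t or F).
#' @param p_map matching p-value [volume_map()].
#' @param forming_p cluster-forming voxelwise p threshold.
#' @param min_extent_k minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @return A list of clusters, each a list with `voxels` (linear indices),
#'   `size`, `peak_stat`, `peak_mni_mm`.
#' @export
extract_clusters <- function(stat_map, p_map, forming_p, min_extent_k = 1,
                             connectivity = 26) {
  dmn_assert(same_grid(stat_map, p_map), "grid_mismatch",
             "stat and p maps are not on one grid")
  supra <- !is.na(p_map$data) & p_map$data < forming_p
  if (!any(supra)) return(list())
  labs <- label_components(supra, connectivity)
  sizes <- tabulate(labs[labs > 0])
  keep <- which(sizes >= min_extent_k)
  if (length(keep) == 0) return(list())
  shape <- dim(stat_map$data)
  out <- lapply(keep, function(l) {
    vox <- which(labs == l)
    stats_v <- stat_map$data[vox]
    pk <- vox[which.max(abs(stats_v))]
    list(voxels = vox, size = length(vox),
         peak_stat = stats_v[which.max(abs(stats_v))],
         peak_mni_mm = as.numeric(vox_to_mm(stat_map$affine,
                                            arrayInd(pk, shape))))
  })
  out[order(vapply(out, `[[`, numeric(1), "size"), decreasing = TRUE)]
}

#' Mean map value over a region of interest
#'
#' @param subject_map a [volume_map()].
#' @param roi a cluster (list with `voxels`), a [binary_mask()], or an
#'   integer vector of linear voxel indices. Missing voxels are ignored.
#' @return Scalar mean.
#' @export
roi_mean <- function(subject_map, roi) {
  vox <- if (inherits(roi, "binary_mask")) which(roi$data)
  else if (is.list(roi)) roi$voxels
  else as.integer(roi)
  dmn_assert(length(vox) > 0, "empty_roi", "ROI contains no voxels")
  vals <- subject_map$data[vox]
  vals <- vals[!is.na(vals)]
  dmn_assert(length(vals) > 0, "empty_roi",
             "ROI is empty after removing missing values")
  mean(vals)
}
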