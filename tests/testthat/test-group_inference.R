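make_group_maps <- function(n_per_group, sh = c(2, 2, 2), seed = 0,
                            shift = c(HC = 0, nonHE = 0, MHE = 0)) {
  set.seed(seed)
  aff <- test_affine()
  groups <- rep(names(n_per_group), n_per_group)
  maps <- lapply(groups, function(g)
    volume_map(array(rnorm(prod(sh)) + shift[[g]], sh), aff, "mean"))
  design <- design_info(groups,
                        age_years = rnorm(length(groups), 50, 8),
                        gender = sample(c("M", "F"), length(groups), TRUE))
  list(maps = maps, design = design,
       mask = binary_mask(array(TRUE, sh), aff))
}

test_that("voxelwise ANOVA matches a brute-force lm oracle", {
  fx <- make_group_maps(c(HC = 4, nonHE = 4, MHE = 4), seed = 0)
  res <- voxelwise_anova(fx$maps, fx$design, fx$mask)
  Y <- vapply(fx$maps, function(m) as.vector(m$data), numeric(8))
  g <- factor(fx$design$group, levels = c("HC", "nonHE", "MHE"))
  for (v in 1:8) {
    full <- lm(Y[v, ] ~ g + fx$design$age_years + fx$design$gender01)
    red <- lm(Y[v, ] ~ fx$design$age_years + fx$design$gender01)
    rss_f <- sum(resid(full)^2); rss_r <- sum(resid(red)^2)
    Fo <- ((rss_r - rss_f) / 2) / (rss_f / full$df.residual)
    expect_equal(res$f_map$data[v], Fo, tolerance = 1e-8)
    expect_equal(res$p_map$data[v],
                 pf(Fo, 2, full$df.residual, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("identical subject values give F = 0, p = 1", {
  fx <- make_group_maps(c(HC = 3, nonHE = 3, MHE = 3), seed = 1)
  maps <- lapply(fx$maps, function(m) {
    m$data[] <- 0.7; m
  })
  res <- voxelwise_anova(maps, fx$design, fx$mask)
  expect_true(all(res$f_map$data == 0))
  expect_true(all(res$p_map$data == 1))
})

test_that("the two-group ANOVA F equals the squared post hoc t", {
  fx <- make_group_maps(c(HC = 6, nonHE = 6), sh = c(3, 3, 2), seed = 2,
                        shift = c(HC = 0, nonHE = 0.4, MHE = 0))
  res_f <- voxelwise_anova(fx$maps, fx$design, fx$mask)
  res_t <- posthoc_t(fx$maps, fx$design, "HC", "nonHE", fx$mask)
  expect_equal(res_f$f_map$data, res_t$t_map$data^2, tolerance = 1e-8)
  expect_equal(res_f$p_map$data, res_t$p_map$data, tolerance = 1e-8)
})

test_that("post hoc t matches the covariate-adjusted lm oracle", {
  fx <- make_group_maps(c(HC = 10, MHE = 10), sh = c(2, 2, 1), seed = 3,
                        shift = c(HC = 0, nonHE = 0, MHE = 0.5))
  res <- posthoc_t(fx$maps, fx$design, "HC", "MHE", fx$mask)
  Y <- vapply(fx$maps, function(m) as.vector(m$data), numeric(4))
  ind <- as.numeric(fx$design$group == "MHE")
  for (v in 1:4) {
    fit <- summary(lm(Y[v, ] ~ ind + fx$design$age_years +
                        fx$design$gender01))
    expect_equal(res$t_map$data[v], fit$coefficients["ind", "t value"],
                 tolerance = 1e-8)
    expect_equal(res$p_map$data[v], fit$coefficients["ind", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
  # swapping the contrast direction flips the sign exactly
  rev <- posthoc_t(fx$maps, fx$design, "MHE", "HC", fx$mask)
  expect_equal(rev$t_map$data, -res$t_map$data, tolerance = 1e-12)
  # identical groups give t = 0
  same <- lapply(seq_along(fx$maps), function(i) fx$maps[[1]])
  res0 <- posthoc_t(same, fx$design, "HC", "MHE", fx$mask)
  expect_true(all(abs(res0$t_map$data) < 1e-8))
})

test_that("smoothness estimation recovers white and known-kernel fields", {
  aff <- test_affine()
  sh <- c(16, 16, 16)
  msk <- binary_mask(array(TRUE, sh), aff)
  set.seed(4)
  white <- lapply(1:8, function(i)
    volume_map(array(rnorm(prod(sh)), sh), aff, "mean"))
  fw <- estimate_smoothness(white, msk)
  expect_true(all(abs(fw - 3) / 3 < 0.15))  # clipped at the 3 mm voxel size

  ker <- dmnfc:::smoothing_kernels(sh, c(3, 3, 3), 8)
  smooth8 <- lapply(1:8, function(i)
    volume_map(dmnfc:::smooth_separable(array(rnorm(prod(sh)), sh), ker),
               aff, "mean"))
  f8 <- estimate_smoothness(smooth8, msk)
  expect_true(all(abs(f8 - 8) / 8 < 0.2))

  const <- lapply(1:2, function(i) volume_map(array(1, sh), aff, "mean"))
  expect_error(estimate_smoothness(const, msk),
               class = "dmnfc_degenerate_residuals")
})

test_that("alphasim min extent: degenerate alpha, monotonicity in forming p", {
  aff <- test_affine()
  msk <- binary_mask(array(TRUE, c(10, 10, 10)), aff)
  base <- cluster_correction(cluster_forming_p = 0.05, alpha = 1.0,
                             n_iterations = 100, smoothness_fwhm_mm = c(3, 3, 3))
  expect_equal(alphasim_min_extent(base, msk, 1)$min_extent_k, 1L)

  ks <- vapply(c(0.05, 0.01, 0.005), function(p) {
    cc <- cluster_correction(cluster_forming_p = p, alpha = 0.05,
                             n_iterations = 300,
                             smoothness_fwhm_mm = c(6, 6, 6))
    alphasim_min_extent(cc, msk, 7)$min_extent_k
  }, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("alphasim agrees with an independent Monte-Carlo implementation", {
  aff <- test_affine()
  sh <- c(8, 8, 8)
  msk <- binary_mask(array(TRUE, sh), aff)
  cc <- cluster_correction(cluster_forming_p = 0.05, alpha = 0.05,
                           n_iterations = 2000,
                           smoothness_fwhm_mm = c(4.5, 4.5, 4.5))
  k_pkg <- alphasim_min_extent(cc, msk, rng_seed = 101)$min_extent_k

  # independent oracle: dense Kronecker smoothing operator with exact
  # row-wise variance normalization, thresholding, and the queue flood fill
  # from the test helpers; different RNG seed
  sig <- 4.5 / (2 * sqrt(2 * log(2))) / 3
  S1 <- dmnfc:::gauss_smooth_matrix(8, sig)
  W <- kronecker(S1, kronecker(S1, S1))
  W <- W / sqrt(rowSums(W^2))
  zc <- qnorm(1 - 0.05 / 2)
  set.seed(999)
  maxes <- vapply(1:2000, function(i) {
    f <- as.vector(W %*% rnorm(512))
    supra <- array(abs(f) > zc, sh)
    if (!any(supra)) return(0L)
    lab <- bf_label(supra, 26)
    max(tabulate(lab[lab > 0]))
  }, integer(1))
  k_oracle <- 1L
  while (k_oracle <= max(maxes) && mean(maxes >= k_oracle) > 0.05)
    k_oracle <- k_oracle + 1L
  expect_lte(abs(k_pkg - k_oracle), 1)
})

test_that("cluster extraction matches a brute-force flood fill", {
  aff <- test_affine()
  set.seed(11)
  for (conn in c(6, 26)) {
    for (rep in 1:4) {
      sh <- c(sample(6:12, 1), sample(6:12, 1), sample(6:12, 1))
      supra <- array(runif(prod(sh)) < 0.25, sh)
      got <- dmnfc:::label_components(supra, conn)
      want <- bf_label(supra, conn)
      expect_true(same_partition(got, want))
    }
  }

  # L-shaped blob: diagonal touch joins under 26- but not 6-connectivity
  sh <- c(5, 5, 3)
  bin <- array(FALSE, sh)
  bin[1:2, 1, 1] <- TRUE
  bin[3, 2, 1] <- TRUE    # touches (2,1,1) only diagonally
  l6 <- dmnfc:::label_components(bin, 6)
  l26 <- dmnfc:::label_components(bin, 26)
  expect_equal(max(l6), 2)
  expect_equal(max(l26), 1)

  # extraction semantics: threshold, minimum extent, ordering, peak
  stat <- array(0, sh); p <- array(1, sh)
  blob1 <- cbind(1:4, 1, 2); blob2 <- cbind(1:2, 4, 3)
  for (i in 1:4) { stat[blob1[i, 1], 1, 2] <- i; p[blob1[i, 1], 1, 2] <- 1e-4 }
  for (i in 1:2) { stat[blob2[i, 1], 4, 3] <- -9; p[blob2[i, 1], 4, 3] <- 1e-4 }
  sm <- volume_map(stat, aff, "F"); pm <- volume_map(p, aff, "p")
  cl_all <- extract_clusters(sm, pm, 0.01, 1, 26)
  expect_length(cl_all, 2)
  expect_equal(vapply(cl_all, `[[`, numeric(1), "size"), c(4, 2))
  expect_equal(cl_all[[1]]$peak_stat, 4)
  expect_equal(cl_all[[1]]$peak_mni_mm,
               as.numeric(vox_to_mm(aff, c(4, 1, 2))))
  cl_k3 <- extract_clusters(sm, pm, 0.01, 3, 26)
  expect_length(cl_k3, 1)
  expect_equal(cl_k3[[1]]$size, 4)
  expect_length(extract_clusters(sm, pm, 1e-6, 1, 26), 0)
})

test_that("roi_mean averages present voxels only", {
  aff <- test_affine()
  m <- volume_map(array(c(0.4, 0.6, NA, 0.52), c(2, 2, 1)), aff, "z")
  expect_equal(roi_mean(m, c(1L, 2L)), 0.5)
  expect_equal(roi_mean(m, list(voxels = c(1L, 2L, 3L))), 0.5)
  u <- volume_map(array(0.52, c(2, 2, 1)), aff, "z")
  msk <- binary_mask(array(TRUE, c(2, 2, 1)), aff)
  expect_equal(roi_mean(u, msk), 0.52)
  expect_error(roi_mean(m, list(voxels = 3L)), class = "dmnfc_empty_roi")
  expect_error(roi_mean(m, integer(0)), class = "dmnfc_empty_roi")
})
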