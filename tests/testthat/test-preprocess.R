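test_that("discard_initial drops exactly the leading volumes once", {
  arr <- array(0, c(3, 3, 3, 250))
  for (t in 1:250) arr[, , , t] <- t
  bold <- make_bold(arr, discarded = FALSE)
  out <- discard_initial(bold, 10)
  expect_equal(dim(out$data)[4], 240)
  expect_true(all(out$data[, , , 1] == 11))
  expect_true(out$discarded)
  expect_error(discard_initial(out, 10), class = "dmnfc_already_discarded")
  expect_error(discard_initial(bold, 250), class = "dmnfc_bad_discard")
  same <- discard_initial(bold, 0)
  expect_identical(same$data, bold$data)
})

test_that("motion screening applies strict exceedance at the printed limits", {
  zeros <- motion_trace(matrix(0, 50, 3), matrix(0, 50, 3))
  expect_false(screen_motion(zeros)$excluded)

  t12 <- zeros; t12$translations_mm[7, 3] <- -1.2
  v <- screen_motion(t12)
  expect_true(v$excluded)
  expect_equal(v$max_translation_mm, 1.2)

  # exactly at the limit: "more than" is strict, the subject is retained
  t10 <- zeros; t10$translations_mm[7, 3] <- 1.0
  expect_false(screen_motion(t10)$excluded)
  r10 <- zeros; r10$rotations_deg[3, 1] <- 1.0
  expect_false(screen_motion(r10)$excluded)
  r11 <- zeros; r11$rotations_deg[3, 1] <- 1.01
  expect_true(screen_motion(r11)$excluded)
})

test_that("Gaussian smoothing preserves constants and matches kernel weights", {
  const <- make_bold(array(7, c(9, 9, 9, 2)))
  sm <- smooth_bold(const, 8)
  expect_equal(sm$data, const$data, tolerance = 1e-12)

  # impulse response: centre value equals the product of the three 1-D
  # truncated, normalized central kernel weights
  arr <- array(0, c(15, 15, 15, 1))
  arr[8, 8, 8, 1] <- 1
  imp <- make_bold(arr)
  out <- smooth_bold(imp, 8)
  sigma <- (8 / (2 * sqrt(2 * log(2)))) / 3       # voxels, 3 mm grid
  r <- max(1, ceiling(4 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w0 <- w[r + 1] / sum(w)
  expect_equal(out$data[8, 8, 8, 1], w0^3, tolerance = 1e-10)

  # interior mass conservation (support far enough from the boundary that no
  # edge-renormalized kernel row receives mass)
  arr2 <- array(0, c(21, 21, 21, 1))
  arr2[9:13, 9:13, 9:13, 1] <- rexp(125)
  out2 <- smooth_bold(make_bold(arr2), 6)
  expect_equal(sum(out2$data), sum(arr2), tolerance = 1e-6)

  expect_error(smooth_bold(const, -1), class = "dmnfc_bad_params")
})

test_that("nuisance regression projects out exactly the design span", {
  set.seed(9)
  nt <- 60
  aff <- test_affine()
  trace <- motion_trace(matrix(rnorm(nt * 3, sd = 0.1), nt, 3),
                        matrix(rnorm(nt * 3, sd = 0.1), nt, 3))
  sh <- c(4, 4, 4)
  csf <- array(FALSE, sh); csf[1, 1, 1] <- TRUE
  wm <- array(FALSE, sh); wm[4, 4, 4] <- TRUE
  brain <- array(TRUE, sh)
  # without global regression the design depends only on the two tissue
  # voxels, so probe series at other voxels never feed back into the design
  cfg <- preprocess_config(nuisance_set = c(motion = TRUE, csf = TRUE,
                                            wm = TRUE, global = FALSE))
  base <- array(rnorm(prod(sh) * nt), c(sh, nt))
  bold <- make_bold(base, discarded = TRUE)
  X <- cbind(1, trace$translations_mm, trace$rotations_deg,
             dmnfc:::mask_mean_series(bold, binary_mask(csf, aff)),
             dmnfc:::mask_mean_series(bold, binary_mask(wm, aff)))

  # a voxel lying exactly in the design span is annihilated
  base2 <- base
  base2[2, 2, 2, ] <- X %*% rnorm(ncol(X))
  # and a voxel orthogonal to the design (explicit Gram-Schmidt) is untouched
  q <- qr.Q(qr(X))
  v <- rnorm(nt)
  v <- as.numeric(v - q %*% crossprod(q, v))
  base2[3, 3, 3, ] <- v
  res <- regress_nuisance(make_bold(base2), trace, binary_mask(csf, aff),
                          binary_mask(wm, aff), binary_mask(brain, aff), cfg)
  expect_lt(max(abs(res$data[2, 2, 2, ])), 1e-8)
  expect_lt(max(abs(res$data[3, 3, 3, ] - v)), 1e-8)

  # residuals orthogonal to every regressor, including the global mean when
  # the full default nuisance set is used
  res_full <- regress_nuisance(make_bold(base2), trace, binary_mask(csf, aff),
                               binary_mask(wm, aff), binary_mask(brain, aff))
  Xf <- cbind(X, dmnfc:::mask_mean_series(make_bold(base2),
                                          binary_mask(brain, aff)))
  ip <- crossprod(Xf, dmnfc:::bold_ts_matrix(res_full))
  expect_lt(max(abs(ip)) / nt, 1e-6)
})

test_that("a collinear nuisance design raises a named error with columns", {
  nt <- 40
  aff <- test_affine()
  trace <- motion_trace(matrix(0, nt, 3), matrix(0, nt, 3))  # constant motion
  sh <- c(3, 3, 3)
  csf <- array(FALSE, sh); csf[1, 1, 1] <- TRUE
  wm <- array(FALSE, sh); wm[3, 3, 3] <- TRUE
  bold <- make_bold(array(rnorm(prod(sh) * nt), c(sh, nt)))
  err <- tryCatch(
    regress_nuisance(bold, trace, binary_mask(csf, aff), binary_mask(wm, aff),
                     binary_mask(array(TRUE, sh), aff)),
    condition = function(c) c)
  expect_s3_class(err, "dmnfc_collinear_design")
  expect_match(conditionMessage(err), "motion")
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  nt <- 240; tr <- 2
  t <- (0:(nt - 1)) * tr
  amp_out <- function(freq) {
    x <- sin(2 * pi * freq * t)
    arr <- array(rep(x, each = 8), c(2, 2, 2, nt))
    out <- bandpass(make_bold(arr, tr = tr), 0.01, 0.08)
    y <- out$data[1, 1, 1, ]
    # FFT oracle: amplitude at the stimulus bin
    k <- freq * nt * tr
    abs(fft(y))[k + 1] / abs(fft(x))[k + 1]
  }
  expect_gte(amp_out(0.05), 0.95)
  expect_lte(amp_out(0.2), 0.05)

  const <- make_bold(array(3, c(2, 2, 2, nt)), tr = tr)
  expect_lt(max(abs(bandpass(const, 0.01, 0.08)$data)), 1e-10)

  expect_error(bandpass(const, 0.05, 0.3), class = "dmnfc_bad_band")
})

test_that("band-pass is linear", {
  set.seed(3)
  nt <- 120
  a <- array(rnorm(8 * nt), c(2, 2, 2, nt))
  b <- array(rnorm(8 * nt), c(2, 2, 2, nt))
  fa <- bandpass(make_bold(a), 0.01, 0.08)$data
  fb <- bandpass(make_bold(b), 0.01, 0.08)$data
  fab <- bandpass(make_bold(2 * a - 3 * b), 0.01, 0.08)$data
  expect_equal(fab, 2 * fa - 3 * fb, tolerance = 1e-10)
})

test_that("the fused preprocessing chain equals the staged operations", {
  sh <- shared_subject()
  s <- sh$raw; masks <- sh$masks
  cfg <- preprocess_config()
  staged <- discard_initial(s$bold, cfg$n_discard)
  staged <- smooth_bold(staged, cfg$smooth_fwhm_mm)
  staged <- regress_nuisance(staged, s$trace, masks$csf, masks$wm,
                             masks$brain, cfg)
  staged <- bandpass(staged, cfg$band_low_hz, cfg$band_high_hz)
  fused <- sh$processed
  expect_equal(fused$data, staged$data, tolerance = 1e-10)
})
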