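test_that("seed_timeseries averages exactly the in-sphere voxels", {
  aff <- test_affine()
  arr <- array(rnorm(6 * 6 * 6 * 20), c(6, 6, 6, 20))
  bold <- make_bold(arr)

  # radius 0: the single voxel containing the centre (voxel [3,3,3] is mm
  # (-12,-12,-12))
  s0 <- seed_timeseries(bold, seed_spec("pt", c(-12, -12, -12), 0))
  expect_equal(s0, arr[3, 3, 3, ])

  # spatially uniform volume: any radius returns the common series
  u <- array(rep(sin(1:20), each = 216), c(6, 6, 6, 20))
  su <- seed_timeseries(make_bold(u), seed_spec("u", c(-10, -10, -10), 5))
  expect_equal(su, sin(1:20))

  # a 2-voxel sphere: radius just covering two neighbours along x
  s2 <- seed_timeseries(bold, seed_spec("two", c(-13.5, -12, -12), 1.6))
  expect_equal(s2, (arr[2, 3, 3, ] + arr[3, 3, 3, ]) / 2)

  expect_error(seed_timeseries(bold, seed_spec("out", c(500, 0, 0), 2)),
               class = "dmnfc_empty_seed")
})

test_that("correlation_map recovers exact and attenuated correlations", {
  set.seed(21)
  nt <- 240
  seed_ts <- as.numeric(arima.sim(list(ar = 0.3), nt))
  arr <- array(rnorm(4 * 4 * 4 * nt), c(4, 4, 4, nt))
  arr[1, 1, 1, ] <- seed_ts
  arr[2, 1, 1, ] <- -seed_ts
  arr[3, 1, 1, ] <- seed_ts + rnorm(nt, sd = sd(seed_ts))  # equal-variance noise
  arr[4, 1, 1, ] <- 5                                       # zero variance
  rmap <- correlation_map(make_bold(arr), seed_ts)
  expect_equal(rmap$data[1, 1, 1], 1.0)
  expect_equal(rmap$data[2, 1, 1], -1.0)
  expect_lt(abs(rmap$data[3, 1, 1] - 1 / sqrt(2)), 0.1)
  expect_true(is.na(rmap$data[4, 1, 1]))
  expect_true(all(abs(rmap$data[is.finite(rmap$data)]) <= 1))
  expect_error(correlation_map(make_bold(arr), rep(1, nt)),
               class = "dmnfc_constant_seed")
})

test_that("fisher_z matches the closed form and inverts through tanh", {
  aff <- test_affine()
  r <- seq(-0.999, 0.999, length.out = 201)
  rmap <- volume_map(array(r, c(201, 1, 1)), aff, "r")
  z <- fisher_z(rmap)
  expect_equal(z$data[101, 1, 1], 0)                       # r = 0
  expect_equal(atanh(0.5), 0.5 * log(3), tolerance = 1e-12)
  r05 <- volume_map(array(0.5, c(1, 1, 1)), aff, "r")
  expect_equal(fisher_z(r05)$data[1, 1, 1], 0.5493, tolerance = 1e-4)
  # odd symmetry and strict monotonicity
  expect_equal(z$data[, 1, 1], -rev(z$data[, 1, 1]), tolerance = 1e-12)
  expect_true(all(diff(z$data[, 1, 1]) > 0))
  # round trip
  expect_equal(tanh(z$data), rmap$data, tolerance = 1e-12)
  # |r| = 1 becomes missing with a warning
  r1 <- volume_map(array(c(1, -1, 0.2), c(3, 1, 1)), aff, "r")
  expect_warning(z1 <- fisher_z(r1), "\\|r\\| = 1")
  expect_true(all(is.na(z1$data[1:2, 1, 1])))
})

test_that("mean_seed_zmap averages voxelwise and propagates missingness", {
  aff <- test_affine()
  mk <- function(v) volume_map(array(v, c(2, 2, 1)), aff, "z")
  m <- mk(c(0.3, 0.6, 0.9, NA))
  expect_equal(mean_seed_zmap(list(m, m, m))$data, m$data)
  avg <- mean_seed_zmap(list(mk(0.3), mk(0.6), mk(0.9)))
  expect_equal(unique(as.vector(avg$data)), 0.6)
  one_na <- mean_seed_zmap(list(mk(c(0.3, NA, 1, 1)), mk(0.6), mk(0.9)))
  expect_true(is.na(one_na$data[2, 1, 1]))
  expect_false(anyNA(one_na$data[1, 1, 1]))
  bad <- volume_map(array(0, c(3, 3, 1)), aff, "z")
  expect_error(mean_seed_zmap(list(m, bad)), class = "dmnfc_grid_mismatch")
})

test_that("fdr_select implements the BH step-up rule exactly", {
  expect_equal(fdr_select(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(fdr_select(c(0.2, 0.5), 0.05), rep(FALSE, 2))
  expect_equal(fdr_select(0.0, 0.05), TRUE)
  expect_error(fdr_select(c(0.5, 1.2), 0.05), class = "dmnfc_bad_params")

  # brute-force enumeration and stats::p.adjust as independent oracles
  set.seed(77)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    got <- fdr_select(p, q)
    expect_identical(got, bf_bh(p, q))
    expect_identical(got, unname(p.adjust(p, "BH") <= q) &
                       (sum(p.adjust(p, "BH") <= q) > 0))
  }
})

test_that("seed significance mask keeps strong consistent effects and
           controls false positives under the null", {
  aff <- test_affine()
  sh <- c(5, 5, 4)
  set.seed(8)
  # one voxel with a strong consistent z across 20 subjects, rest null
  maps <- lapply(1:20, function(i) {
    d <- array(rnorm(prod(sh), sd = 0.05), sh)
    d[2, 3, 2] <- 0.8 + rnorm(1, sd = 0.01)
    volume_map(d, aff, "z")
  })
  msk <- seed_significance_mask(maps, q = 0.05)
  expect_true(msk$data[2, 3, 2])

  # all-null cohorts: any selection is a false discovery; under BH the rate
  # of cohorts with any selection stays near or below q
  hits <- vapply(1:60, function(i) {
    nm <- lapply(1:20, function(j)
      volume_map(array(rnorm(prod(sh)), sh), aff, "z"))
    any(seed_significance_mask(nm, q = 0.05)$data)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))

  # single-voxel grid reduces to a single test at level q
  one <- lapply(1:5, function(i)
    volume_map(array(0.5 + rnorm(1, sd = 0.1), c(1, 1, 1)), aff, "z"))
  Z <- vapply(one, function(m) m$data[1, 1, 1], numeric(1))
  pt_p <- t.test(Z)$p.value
  expect_equal(any(seed_significance_mask(one, 0.05)$data), pt_p <= 0.05)

  expect_error(seed_significance_mask(maps[1:2], 0.05),
               class = "dmnfc_too_few_subjects")
})

test_that("conjunction requires at least 2 of 3 seeds", {
  aff <- test_affine()
  sh <- c(3, 3, 3)
  mk <- function(idx) {
    d <- array(FALSE, sh); d[idx] <- TRUE
    binary_mask(d, aff)
  }
  m1 <- mk(c(1, 2, 3)); m2 <- mk(c(2, 3, 4)); m3 <- mk(c(3, 9))
  conj <- conjunction(list(m1, m2, m3))
  expect_true(conj$data[2])            # in exactly 2 masks
  expect_true(conj$data[3])            # in all 3
  expect_false(conj$data[1])           # in exactly 1
  expect_false(conj$data[9])
  # idempotence and set bounds
  expect_identical(conjunction(list(m1, m1, m1))$data, m1$data)
  expect_true(all(!conj$data | (m1$data | m2$data | m3$data)))
  expect_true(all(!(m1$data & m2$data & m3$data) | conj$data))
  empty <- mk(integer(0))
  expect_false(any(conjunction(list(empty, empty, empty))$data))
})

# The planted-node coverage property of the conjunction mask (>= 90% of node
# voxels in, background out) needs a cohort on the full default grid and is
# asserted on the parameter-recovery cohort in test-acceptance.R.
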