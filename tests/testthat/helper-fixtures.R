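# Shared fixtures and independent brute-force oracles.

test_affine <- function(vox = c(3, 3, 3), origin = c(-18, -18, -18)) {
  a <- diag(c(vox, 1))
  a[1:3, 4] <- origin
  a
}

# Desk-scale cohort on a 12^3 grid with three planted nodes; full-length
# acquisition (250 volumes, TR 2 s, 10 discarded).
tiny_cohort_config <- function(n_per_group = c(HC = 8, nonHE = 8, MHE = 8),
                               rho_by_group = c(HC = 0.6, nonHE = 0.45,
                                                MHE = 0.3),
                               master_seed = 1, ...) {
  cohort_config(n_per_group = n_per_group,
                grid_shape = c(12, 12, 12), origin_mm = c(-18, -18, -18),
                node_specs = data.frame(
                  name = c("A", "B", "C"),
                  x = c(-9, 6, 0), y = c(6, -9, 0), z = c(0, 3, -9),
                  radius_mm = 4.5, stringsAsFactors = FALSE),
                rho_by_group = rho_by_group, master_seed = master_seed, ...)
}

tiny_seeds <- function() {
  list(seed_spec("A", c(-9, 6, 0), 4.5),
       seed_spec("B", c(6, -9, 3), 4.5),
       seed_spec("C", c(0, 0, -9), 4.5))
}

tiny_run_config <- function(...) {
  run_config(seeds = tiny_seeds(), ...)
}

make_bold <- function(data, affine = test_affine(), tr = 2, discarded = TRUE,
                      n_discard = 0) {
  d <- dim(data)
  nv <- if (discarded) d[4] + n_discard else d[4]
  bold_series(data, affine,
              acq_params(tr, nv, n_discard,
                         voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2))),
              discarded = discarded)
}

# --- independent oracles ----------------------------------------------------

# Benjamini-Hochberg by direct enumeration of the step-up definition.
bf_bh <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ps <- sort(p)
  thr <- NA_real_
  for (i in m:1) {
    if (ps[i] <= i * q / m) { thr <- ps[i]; break }
  }
  if (is.na(thr)) rep(FALSE, m) else p <= thr
}

# AUC as pairwise concordance, orientation "lower value indicates disease":
# a case-control pair is concordant when case < control; ties count half.
bf_auc <- function(case, ctrl) {
  s <- 0
  for (x in case) for (y in ctrl)
    s <- s + (x < y) + 0.5 * (x == y)
  s / (length(case) * length(ctrl))
}

# flood fill over an explicit voxel queue, written independently of the
# package internals
bf_label <- function(bin, connectivity = 26) {
  sh <- dim(bin)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, sh)
  cur_lab <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    cur_lab <- cur_lab + 1L
    queue <- list(arrayInd(start, sh)[1, ])
    lab[start] <- cur_lab
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (any(w < 1) || any(w > sh)) next
        li <- w[1] + sh[1] * (w[2] - 1 + sh[2] * (w[3] - 1))
        if (bin[li] && lab[li] == 0L) {
          lab[li] <- cur_lab
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  lab
}

# do two labelings define the same partition of the foreground?
same_partition <- function(a, b) {
  fa <- a[a > 0]; fb <- b[b > 0]
  if (length(fa) != length(fb)) return(FALSE)
  if (!all((a > 0) == (b > 0))) return(FALSE)
  key <- paste(fa, fb)
  length(unique(key)) == length(unique(fa)) &&
    length(unique(key)) == length(unique(fb))
}

# one preprocessed tiny subject, shared across test files that only need
# "some realistic series"
shared_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_cohort_config(master_seed = 42)
      s <- simulate_subject(cfg, "HC", 1)
      masks <- cohort_masks(cfg)
      cache <<- list(raw = s, masks = masks, config = cfg,
                     processed = preprocess_subject(s$bold, s$trace,
                                                    masks$csf, masks$wm,
                                                    masks$brain))
    }
    cache
  }
})
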