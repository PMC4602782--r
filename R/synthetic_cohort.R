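#' Synthetic cohort configuration
#'
#' Describes a synthetic resting-state study: grid geometry, acquisition
#' parameters, DMN node spheres, per-group planted inter-node correlation,
#' and noise/nuisance amplitudes. Defaults emulate the acquisition used in
#' clinical MHE studies (250 volumes at TR 2 s, of which the first 10 are
#' discarded, on a 3 mm isotropic grid) on a compact field of view that
#' contains the three canonical DMN seed coordinates (MPFC -1,47,-4;
#' PCC -5,-49,40; left LP -45,-67,36) plus surrogate SFG and bilateral MTG
#' nodes. Planted correlation decreases from healthy controls through non-HE
#' to MHE, and neuropsychological scores are coupled to the planted
#' connectivity (longer NCT-A and lower DST for weaker connectivity).
#'
#' @param n_per_group named integer triple `c(HC=, nonHE=, MHE=)`.
#' @param grid_shape integer triple of voxel counts per axis.
#' @param voxel_size_mm positive triple (mm).
#' @param origin_mm mm coordinate of the first voxel centre.
#' @param acquisition an [acq_params()].
#' @param node_specs data.frame with columns `name, x, y, z, radius_mm`
#'   giving DMN node spheres in MNI mm.
#' @param rho_by_group named numeric `c(HC=, nonHE=, MHE=)`, each in `[0, 1)`:
#'   planted inter-node temporal correlation.
#' @param rho_jitter_sd between-subject SD of the planted correlation.
#' @param noise_sd SD of additive broadband Gaussian noise (the network
#'   signal has unit variance, so this is an inverse SNR).
#' @param drift_amplitude SD of per-voxel linear drift slope over the run.
#' @param nuisance_amplitude mean per-voxel gain of the two shared nuisance
#'   signals (a respiratory-like 0.12 Hz oscillation and a very slow 0.005 Hz
#'   sway, both outside the 0.01-0.08 Hz analysis band).
#' @param motion_sd_mm innovation SD of the AR(1) motion parameter traces
#'   (mm for translations, degrees for rotations).
#' @param neuropsych_coupling slope linking planted connectivity to the test
#'   score means: NCT-A mean falls and DST mean rises with connectivity.
#' @param master_seed integer master RNG seed; together with each subject's
#'   seed it makes every output deterministic.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(HC = 20, nonHE = 20, MHE = 20),
                          grid_shape = c(24, 44, 24),
                          voxel_size_mm = c(3, 3, 3),
                          origin_mm = c(-60, -76, -22),
                          acquisition = acq_params(tr_seconds = 2,
                                                   n_volumes = 250,
                                                   n_discard = 10,
                                                   voxel_size_mm = voxel_size_mm),
                          node_specs = default_dmn_nodes(),
                          rho_by_group = c(HC = 0.6, nonHE = 0.45, MHE = 0.3),
                          rho_jitter_sd = 0.05,
                          noise_sd = 1.0,
                          drift_amplitude = 0.5,
                          nuisance_amplitude = 0.4,
                          motion_sd_mm = 0.03,
                          neuropsych_coupling = 80,
                          master_seed = 1L) {
  dmn_assert(all(c("HC", "nonHE", "MHE") %in% names(n_per_group)),
             "bad_config", "n_per_group needs HC, nonHE, MHE entries")
  dmn_assert(all(c("HC", "nonHE", "MHE") %in% names(rho_by_group)),
             "bad_config", "rho_by_group needs HC, nonHE, MHE entries")
  dmn_assert(all(rho_by_group >= 0 & rho_by_group < 1),
             "bad_config", "rho values must satisfy 0 <= rho < 1")
  affine <- diag(c(voxel_size_mm, 1))
  affine[1:3, 4] <- origin_mm
  lo <- origin_mm
  hi <- origin_mm + (grid_shape - 1) * voxel_size_mm
  for (i in seq_len(nrow(node_specs))) {
    ctr <- as.numeric(node_specs[i, c("x", "y", "z")])
    r <- node_specs$radius_mm[i]
    dmn_assert(all(ctr - r >= lo - 1e-9) && all(ctr + r <= hi + 1e-9),
               "bad_config",
               sprintf("node '%s' sphere does not fit inside the grid",
                       node_specs$name[i]))
  }
  structure(list(n_per_group = n_per_group, grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, origin_mm = origin_mm,
                 affine = affine, acquisition = acquisition,
                 node_specs = node_specs, rho_by_group = rho_by_group,
                 rho_jitter_sd = rho_jitter_sd, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 nuisance_amplitude = nuisance_amplitude,
                 motion_sd_mm = motion_sd_mm,
                 neuropsych_coupling = neuropsych_coupling,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_dmn_nodes <- function() {
  data.frame(
    name = c("MPFC", "PCC", "LP", "SFG_L", "MTG_L", "MTG_R_surrogate"),
    x = c(-1, -5, -45, -20, -52, 3),
    y = c(47, -49, -67, 38, -40, -40),
    z = c(-4, 40, 36, 40, -10, -10),
    radius_mm = 6,
    stringsAsFactors = FALSE)
}

# deterministic per-subject RNG seed below 2^31
mix_seed <- function(master_seed, subject_seed) {
  as.integer((as.numeric(master_seed) * 48271 +
                as.numeric(subject_seed) * 16807 + 12345) %% 2147483647)
}

#' Ground-truth node voxel sets
#'
#' Linear (column-major) voxel indices of each configured DMN node sphere —
#' the planted ground truth that validation compares recovered clusters
#' against. Never consumed by the analysis pipeline itself.
#'
#' @param config a [cohort_config()].
#' @return A list of integer vectors, one per node, in `node_specs` order.
#' @export
node_voxel_sets <- function(config) {
  lapply(seq_len(nrow(config$node_specs)), function(i) {
    which(sphere_voxels(config$grid_shape, config$affine,
                        as.numeric(config$node_specs[i, c("x", "y", "z")]),
                        config$node_specs$radius_mm[i]))
  })
}

#' Tissue masks of the synthetic phantom
#'
#' The whole grid counts as brain; CSF and white matter are fixed corner
#' blocks kept clear of the node spheres. These are the masks the nuisance
#' regression consumes.
#'
#' @param config a [cohort_config()].
#' @return A list with `brain`, `csf`, `wm` ([binary_mask()]s) and
#'   `node_labels` (a [volume_map()] labelling node voxels by node index).
#' @export
cohort_masks <- function(config) {
  sh <- config$grid_shape
  brain <- array(TRUE, sh)
  csf <- array(FALSE, sh)
  csf[1:min(3, sh[1]), 1:min(4, sh[2]), 1:min(3, sh[3])] <- TRUE
  wm <- array(FALSE, sh)
  wm[1:min(3, sh[1]), (sh[2] - min(3, sh[2] - 1)):sh[2],
     (sh[3] - min(2, sh[3] - 1)):sh[3]] <- TRUE
  nodes <- array(0L, sh)
  sets <- node_voxel_sets(config)
  for (i in seq_along(sets)) nodes[sets[[i]]] <- i
  csf[nodes > 0] <- FALSE
  wm[nodes > 0] <- FALSE
  list(brain = binary_mask(brain, config$affine),
       csf = binary_mask(csf, config$affine),
       wm = binary_mask(wm, config$affine),
       node_labels = volume_map(nodes * 1.0, config$affine, kind = "mean"))
}

# band-limited unit-variance Gaussian signals, one per column
bandlimited_signals <- function(n_t, n_sig, tr, low = 0.01, high = 0.08) {
  W <- matrix(stats::rnorm(n_t * n_sig), n_t, n_sig)
  S <- bandpass_matrix(W, tr, low, high)
  sds <- sqrt(colMeans(S^2) - colMeans(S)^2)
  sds[sds == 0] <- 1
  sweep(S, 2, sds, "/")
}

ar1_trace <- function(n, sd, phi = 0.95) {
  e <- matrix(stats::rnorm(n * 6, sd = sd), n, 6)
  apply(e, 2, function(x) as.numeric(stats::filter(x, phi, "recursive")))
}

#' Simulate one synthetic subject
#'
#' Builds a BOLD series in which every voxel of every DMN node carries
#' `sqrt(rho) * n(t) + sqrt(1 - rho) * u_v(t)` — a shared band-limited
#' (0.01-0.08 Hz) network signal plus a voxel-unique band-limited signal,
#' rescaled to unit variance — while non-node voxels carry noise and nuisance
#' only. All voxels receive broadband Gaussian noise, a per-voxel linear
#' drift, and two spatially weighted shared nuisance signals. `rho` is the
#' group's planted correlation plus a per-subject jitter. NCT-A completion
#' time decreases and DST score increases with the subject's planted
#' connectivity. Deterministic given `(master_seed, subject_seed)`.
#'
#' @param config a [cohort_config()].
#' @param group `"HC"`, `"nonHE"` or `"MHE"`.
#' @param subject_seed integer distinguishing subjects under one master seed.
#' @return A list with elements `bold` ([bold_series()]), `trace`
#'   ([motion_trace()]), `record` (one-row data.frame of manifest fields) and
#'   `truth` (one-row data.frame: subject_id, group, rho_planted,
#'   n_node_voxels).
#' @export
simulate_subject <- function(config, group, subject_seed) {
  dmn_assert(group %in% names(config$rho_by_group), "bad_group",
             sprintf("group '%s' is not configured", group))
  set.seed(mix_seed(config$master_seed, subject_seed))
  sh <- config$grid_shape
  n_vox <- prod(sh)
  n_t <- config$acquisition$n_volumes
  tr <- config$acquisition$tr_seconds

  rho <- config$rho_by_group[[group]] +
    stats::rnorm(1, sd = config$rho_jitter_sd)
  rho <- min(max(rho, 0), 0.95)

  node_idx <- sort(unique(unlist(node_voxel_sets(config))))

  # noise + drift + shared nuisance everywhere
  Y <- matrix(stats::rnorm(n_t * n_vox, sd = config$noise_sd), n_t, n_vox)
  ramp <- seq(-0.5, 0.5, length.out = n_t)
  slopes <- stats::rnorm(n_vox, sd = config$drift_amplitude)
  Y <- Y + tcrossprod(ramp, slopes)
  tt <- (seq_len(n_t) - 1) * tr
  resp <- sin(2 * pi * 0.12 * tt + stats::runif(1, 0, 2 * pi))
  slow <- sin(2 * pi * 0.005 * tt + stats::runif(1, 0, 2 * pi))
  na <- config$nuisance_amplitude
  Y <- Y + tcrossprod(resp, stats::rnorm(n_vox, na, na / 4)) +
    tcrossprod(slow, stats::rnorm(n_vox, na, na / 4))

  # planted network signal on node voxels
  latent <- bandlimited_signals(n_t, 1, tr)[, 1]
  U <- bandlimited_signals(n_t, length(node_idx), tr)
  comp <- sqrt(rho) * latent + sqrt(1 - rho) * U
  sds <- sqrt(colMeans(comp^2) - colMeans(comp)^2)
  comp <- sweep(comp, 2, sds, "/")
  Y[, node_idx] <- Y[, node_idx] + comp

  bold <- bold_series(array(t(Y), dim = c(sh, n_t)), config$affine,
                      config$acquisition, discarded = FALSE)
  trace <- motion_trace(ar1_trace(n_t, config$motion_sd_mm)[, 1:3],
                        ar1_trace(n_t, config$motion_sd_mm)[, 1:3])

  age <- min(max(stats::rnorm(1, 48, 10.2), 18), 78)
  gender <- if (stats::runif(1) < 0.74) "M" else "F"
  nct <- max(90 - config$neuropsych_coupling * rho + stats::rnorm(1, 0, 6), 15)
  dst <- max(round(20 + 0.5 * config$neuropsych_coupling * rho +
                     stats::rnorm(1, 0, 3)), 0)
  sid <- sprintf("%s%03d", gsub("[^A-Za-z]", "", group), subject_seed)
  record <- data.frame(subject_id = sid, group = group,
                       age_years = round(age, 1), gender = gender,
                       nct_a_seconds = round(nct, 1), dst_score = dst,
                       bold_path = "", motion_path = "",
                       stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = sid, group = group, rho_planted = rho,
                      n_node_voxels = length(node_idx),
                      stringsAsFactors = FALSE)
  list(bold = bold, trace = trace, record = record, truth = truth)
}

#' Simulate a full cohort
#'
#' Generates `n_per_group` subjects per group. With `out_dir` set, writes the
#' BOLD NIfTI and motion text file per subject, the tissue and node-label
#' masks, a manifest TSV referencing them, and a ground-truth TSV (planted
#' per-subject correlation; never consumed by the analysis pipeline). With
#' `out_dir = NULL` everything is returned in memory.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing), or `NULL`.
#' @return Invisibly (or visibly when in-memory), a list with `subjects`
#'   (list of [simulate_subject()] results), `manifest`, `truth`, `masks`,
#'   and, when written, `manifest_path`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  groups <- rep(c("HC", "nonHE", "MHE"),
                times = config$n_per_group[c("HC", "nonHE", "MHE")])
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups))
    subjects[[i]] <- simulate_subject(config, groups[i], i)
  manifest <- do.call(rbind, lapply(subjects, `[[`, "record"))
  truth <- do.call(rbind, lapply(subjects, `[[`, "truth"))
  masks <- cohort_masks(config)
  out <- list(subjects = subjects, manifest = manifest, truth = truth,
              masks = masks, config = config)
  if (is.null(out_dir)) return(out)

  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dmn_assert(dir.exists(out_dir), "unwritable",
             sprintf("cannot create output directory %s", out_dir))
  for (i in seq_along(subjects)) {
    sid <- manifest$subject_id[i]
    bp <- file.path(out_dir, paste0(sid, "_bold.nii.gz"))
    mp <- file.path(out_dir, paste0(sid, "_motion.txt"))
    write_bold(subjects[[i]]$bold, bp)
    write_motion(subjects[[i]]$trace, mp)
    manifest$bold_path[i] <- bp
    manifest$motion_path[i] <- mp
  }
  write_map(masks$brain, file.path(out_dir, "brain_mask.nii.gz"))
  write_map(masks$csf, file.path(out_dir, "csf_mask.nii.gz"))
  write_map(masks$wm, file.path(out_dir, "wm_mask.nii.gz"))
  write_map(masks$node_labels, file.path(out_dir, "node_labels.nii.gz"))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$manifest <- manifest
  out$manifest_path <- manifest_path
  invisible(out)
}

#' Lazy per-subject generators for a configured cohort
#'
#' Returns one zero-argument function per subject (groups in HC, nonHE, MHE
#' order), each producing the [simulate_subject()] result on call. Passing
#' these to [analyze_cohort()] keeps only one subject's BOLD series in
#' memory at a time, which is what makes full-size synthetic studies fit in
#' a few hundred MB instead of several GB.
#'
#' @param config a [cohort_config()].
#' @return A list of functions.
#' @export
subject_loaders <- function(config) {
  groups <- rep(c("HC", "nonHE", "MHE"),
                times = config$n_per_group[c("HC", "nonHE", "MHE")])
  lapply(seq_along(groups), function(i) {
    force(i)
    function() simulate_subject(config, groups[i], i)
  })
}

#' Inject a motion outlier into a trace
#'
#' Sets one volume's x-translation to `magnitude_mm`, leaving everything else
#' unchanged; with magnitude 0 the trace is returned untouched. Used to test
#' the motion-screening exclusion rule.
#'
#' @param trace a [motion_trace()].
#' @param magnitude_mm translation magnitude to plant (>= 0).
#' @param volume which volume to corrupt (default: middle of the run).
#' @return The modified [motion_trace()].
#' @export
inject_motion_outlier <- function(trace, magnitude_mm,
                                  volume = ceiling(nrow(trace$translations_mm) / 2)) {
  dmn_assert(magnitude_mm >= 0, "bad_params", "magnitude_mm must be >= 0")
  if (magnitude_mm == 0) return(trace)
  trace$translations_mm[volume, 1] <- magnitude_mm
  trace
}
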