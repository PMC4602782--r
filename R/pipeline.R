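#' Run configuration for the full analysis
#'
#' Aggregates per-stage settings: preprocessing, the three DMN seeds, the
#' conjunction FDR rate, cluster correction, ROC orientation, and the master
#' seed used for the Monte-Carlo correction.
#'
#' @param preprocess a [preprocess_config()].
#' @param seeds list of 3 [seed_spec()]s.
#' @param conjunction_q FDR rate for the per-seed significance masks.
#' @param correction a [cluster_correction()]; its smoothness field is
#'   overwritten by the estimate from the ANOVA residuals.
#' @param analysis_mask `"conjunction"` to run group inference inside the
#'   control-derived DMN conjunction mask, `"brain"` to use the whole brain
#'   mask (the same mask is always used for the Monte-Carlo null).
#' @param roc_orientation `"lower"`: reduced connectivity indicates MHE.
#' @param master_seed integer seed for the Monte-Carlo correction.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       seeds = default_dmn_seeds(),
                       conjunction_q = 0.05,
                       correction = cluster_correction(),
                       analysis_mask = c("conjunction", "brain"),
                       roc_orientation = "lower",
                       master_seed = 1L) {
  structure(list(preprocess = preprocess, seeds = seeds,
                 conjunction_q = conjunction_q, correction = correction,
                 analysis_mask = match.arg(analysis_mask),
                 roc_orientation = roc_orientation,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Build configurations from a YAML file
#'
#' One YAML file carries per-module blocks mirroring the configuration
#' constructors: a `cohort` block ([cohort_config()] fields, with
#' `node_specs` as a list of name/x/y/z/radius_mm rows), a `preprocess`
#' block, a `seeds` list, a `correction` block ([cluster_correction()]
#' fields), plus top-level `conjunction_q`, `analysis_mask`,
#' `roc_orientation` and `master_seed`. Absent fields keep their defaults.
#'
#' @param path YAML file path.
#' @return `cohort_config_from_yaml`: a [cohort_config()];
#'   `run_config_from_yaml`: a [run_config()].
#' @export
cohort_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  blk <- y$cohort
  if (is.null(blk)) blk <- list()
  if (!is.null(blk$node_specs))
    blk$node_specs <- do.call(rbind, lapply(blk$node_specs, as.data.frame))
  for (f in c("n_per_group", "rho_by_group"))
    if (!is.null(blk[[f]])) blk[[f]] <- unlist(blk[[f]])
  if (!is.null(blk$acquisition))
    blk$acquisition <- do.call(acq_params, blk$acquisition)
  do.call(cohort_config, blk)
}

#' @rdname cohort_config_from_yaml
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$preprocess)) {
    pp <- y$preprocess
    if (!is.null(pp$nuisance_set)) pp$nuisance_set <- unlist(pp$nuisance_set)
    args$preprocess <- do.call(preprocess_config, pp)
  }
  if (!is.null(y$seeds))
    args$seeds <- lapply(y$seeds, function(s)
      seed_spec(s$name, c(s$x, s$y, s$z),
                if (is.null(s$radius_mm)) 6 else s$radius_mm))
  if (!is.null(y$correction))
    args$correction <- do.call(cluster_correction, y$correction)
  for (f in c("conjunction_q", "analysis_mask", "roc_orientation",
              "master_seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(run_config, args)
}

#' Simulate a cohort to disk
#'
#' Thin wrapper over [simulate_cohort()] that logs the manifest path.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @return The manifest path, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  res <- simulate_cohort(config, out_dir)
  message("manifest written: ", res$manifest_path)
  invisible(res$manifest_path)
}

#' Analyze an in-memory cohort
#'
#' The full analysis chain on already-loaded subjects: motion screening,
#' per-subject preprocessing (discard, smooth, nuisance regression,
#' band-pass), three-seed z maps, control-derived conjunction DMN mask,
#' voxelwise covariate-adjusted ANOVA, Monte-Carlo cluster-extent
#' correction, post hoc pairwise t tests inside significant clusters,
#' per-subject ROI means, neuropsychological correlations across all
#' patients, and per-ROI ROC discrimination of MHE from non-HE.
#'
#' @param subjects list of subjects, each either a subject list (`bold`,
#'   `trace`, `record`) as produced by [simulate_subject()], or a
#'   zero-argument function returning one (see [subject_loaders()]). Lazy
#'   subjects are materialized one at a time and reduced to their seed
#'   z maps immediately, so full-size studies stay within a few hundred MB.
#' @param masks list with `brain`, `csf`, `wm` [binary_mask()]s.
#' @param config a [run_config()].
#' @param verbose log stage progress via `message()`.
#' @return An object of class `dmn_analysis`: excluded-subject table,
#'   conjunction result, F/p maps, correction (with `min_extent_k`),
#'   clusters, cluster/posthoc/ROI/correlation/ROC tables, and parameters.
#' @export
analyze_cohort <- function(subjects, masks, config = run_config(),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  n_in <- length(subjects)
  say("stage: per-subject screening, preprocessing and seed mapping (",
      n_in, " subjects)")
  dmn_assert(length(config$seeds) == 3, "bad_params", "expected 3 seeds")
  records <- NULL
  verdicts <- vector("list", n_in)
  seed_z <- list(list(), list(), list())
  mean_z <- list()
  kept <- logical(n_in)
  for (i in seq_len(n_in)) {
    s <- if (is.function(subjects[[i]])) subjects[[i]]() else subjects[[i]]
    records <- rbind(records, s$record)
    v <- screen_motion(s$trace, config$preprocess)
    verdicts[[i]] <- v
    if (v$excluded) next
    kept[i] <- TRUE
    processed <- preprocess_subject(s$bold, s$trace, masks$csf, masks$wm,
                                    masks$brain, config$preprocess)
    zs <- lapply(config$seeds, function(sd)
      fisher_z(correlation_map(processed, seed_timeseries(processed, sd))))
    for (k in 1:3) seed_z[[k]][[length(mean_z) + 1]] <- zs[[k]]
    mean_z[[length(mean_z) + 1]] <- mean_seed_zmap(zs)
  }
  excluded <- data.frame(
    subject_id = records$subject_id,
    excluded = !kept,
    max_translation_mm = vapply(verdicts, `[[`, numeric(1),
                                "max_translation_mm"),
    max_rotation_deg = vapply(verdicts, `[[`, numeric(1), "max_rotation_deg"))
  dmn_assert(sum(kept) >= 7, "too_few_subjects",
             "too few subjects survive motion screening to fit the group model")
  records <- records[kept, , drop = FALSE]

  # diagnose undiagnosed cirrhotic patients from control-derived norms
  if (any(records$group == "cirrhotic-undiagnosed")) {
    say("stage: MHE diagnosis")
    norms <- norms_from_controls(records[records$group == "HC", ])
    idx <- which(records$group == "cirrhotic-undiagnosed")
    records$group[idx] <- vapply(idx, function(i)
      diagnose_mhe(records[i, ], norms), character(1))
  }

  say("stage: conjunction mask")
  reference <- records$group == "HC"
  seed_masks <- lapply(seed_z, function(zl)
    seed_significance_mask(zl[reference], config$conjunction_q))
  conj <- list(mean_z_maps = mean_z, seed_z_maps = seed_z,
               seed_masks = seed_masks, dmn_mask = conjunction(seed_masks))
  analysis_mask <- if (config$analysis_mask == "conjunction") {
    binary_mask(conj$dmn_mask$data & masks$brain$data, masks$brain$affine)
  } else masks$brain
  dmn_assert(any(analysis_mask$data), "empty_mask",
             "analysis mask is empty; no voxels to test")

  say("stage: voxelwise ANOVA (", sum(analysis_mask$data), " voxels)")
  design <- design_info(records$group, records$age_years, records$gender)
  aov_res <- voxelwise_anova(conj$mean_z_maps, design, analysis_mask)

  say("stage: Monte-Carlo cluster correction")
  fwhm <- estimate_smoothness(aov_res$residual_maps, analysis_mask)
  correction <- config$correction
  correction$smoothness_fwhm_mm <- fwhm
  correction <- alphasim_min_extent(correction, analysis_mask,
                                    rng_seed = config$master_seed)
  clusters <- extract_clusters(aov_res$f_map, aov_res$p_map,
                               correction$cluster_forming_p,
                               correction$min_extent_k,
                               correction$connectivity)
  say("found ", length(clusters), " significant cluster(s), min extent k = ",
      correction$min_extent_k)

  cluster_table <- roi_table <- posthoc_table <- cor_table <- roc_table <- NULL
  if (length(clusters) > 0) {
    say("stage: post hoc contrasts, ROI means, correlations, ROC")
    pairs <- list(c("HC", "nonHE"), c("HC", "MHE"), c("nonHE", "MHE"))
    roi_means <- vapply(clusters, function(cl)
      vapply(conj$mean_z_maps, roi_mean, numeric(1), roi = cl),
      numeric(length(conj$mean_z_maps)))
    roi_means <- matrix(roi_means, nrow = length(conj$mean_z_maps))
    labels <- sprintf("cluster_%02d", seq_along(clusters))

    cluster_table <- do.call(rbind, lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      gm <- tapply(roi_means[, i], records$group, mean)
      data.frame(label = labels[i], size = cl$size,
                 peak_x = cl$peak_mni_mm[1], peak_y = cl$peak_mni_mm[2],
                 peak_z = cl$peak_mni_mm[3],
                 peak_F = cl$peak_stat,
                 mean_z_HC = unname(gm["HC"]),
                 mean_z_nonHE = unname(gm["nonHE"]),
                 mean_z_MHE = unname(gm["MHE"]))
    }))

    posthoc_table <- do.call(rbind, lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      cl_arr <- array(FALSE, dim(analysis_mask$data))
      cl_arr[cl$voxels] <- TRUE
      cl_mask <- binary_mask(cl_arr, analysis_mask$affine)
      do.call(rbind, lapply(pairs, function(pr) {
        ph <- posthoc_t(conj$mean_z_maps, design, pr[1], pr[2], cl_mask)
        pk <- which.max(abs(ph$t_map$data))
        data.frame(label = labels[i], contrast = paste(pr[2], "minus", pr[1]),
                   peak_t = ph$t_map$data[pk], peak_p = ph$p_map$data[pk])
      }))
    }))

    roi_table <- data.frame(subject_id = records$subject_id,
                            group = records$group)
    for (i in seq_along(clusters)) roi_table[[labels[i]]] <- roi_means[, i]

    pat <- records$group %in% c("MHE", "nonHE")
    if (sum(pat) >= 3) {
      cor_table <- do.call(rbind, lapply(seq_along(clusters), function(i) {
        rn <- pearson_with_scores(roi_means[pat, i],
                                  records$nct_a_seconds[pat])
        rd <- pearson_with_scores(roi_means[pat, i], records$dst_score[pat])
        data.frame(label = labels[i],
                   nct_a_r = rn$r, nct_a_p = rn$p,
                   dst_r = rd$r, dst_p = rd$p, n = rn$n)
      }))
    }
    if (any(records$group == "MHE") && any(records$group == "nonHE")) {
      roc_table <- do.call(rbind, lapply(seq_along(clusters), function(i) {
        roc <- roc_curve(roi_means[pat, i], records$group[pat],
                         orientation = config$roc_orientation)
        data.frame(label = labels[i], auc = roc$auc, cutoff = roc$cutoff,
                   sensitivity = roc$sens_at_cutoff,
                   specificity = roc$spec_at_cutoff)
      }))
    }
  }

  structure(list(excluded = excluded, records = records,
                 conjunction = conj, anova = aov_res,
                 correction = correction, clusters = clusters,
                 cluster_table = cluster_table, posthoc_table = posthoc_table,
                 roi_table = roi_table, cor_table = cor_table,
                 roc_table = roc_table, analysis_mask = analysis_mask,
                 smoothness_fwhm_mm = fwhm, config = config),
            class = "dmn_analysis")
}

#' Analyze a cohort from a manifest on disk
#'
#' Reads the manifest, BOLD/motion files and tissue masks, runs
#' [analyze_cohort()], and writes the result tables (clusters, post hoc,
#' ROI means, correlations, ROC, exclusions), the F/p/DMN-mask volumes, and
#' a run-metadata YAML echoing every parameter.
#'
#' @param manifest_path manifest TSV path (see [read_manifest()]).
#' @param out_dir output directory for result files.
#' @param config a [run_config()].
#' @param mask_dir directory holding `brain_mask.nii.gz`, `csf_mask.nii.gz`,
#'   `wm_mask.nii.gz` (default: the manifest's directory).
#' @param verbose log stage progress.
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_analyze <- function(manifest_path, out_dir, config = run_config(),
                        mask_dir = dirname(manifest_path), verbose = TRUE) {
  manifest <- read_manifest(manifest_path)
  masks <- list(brain = read_mask(file.path(mask_dir, "brain_mask.nii.gz")),
                csf = read_mask(file.path(mask_dir, "csf_mask.nii.gz")),
                wm = read_mask(file.path(mask_dir, "wm_mask.nii.gz")))
  # lazy loaders: one subject's BOLD in memory at a time
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    force(i)
    function() {
      row <- manifest[i, , drop = FALSE]
      bold <- read_bold(row$bold_path, n_discard = config$preprocess$n_discard)
      trace <- read_motion(row$motion_path, bold$params$n_volumes)
      list(bold = bold, trace = trace, record = row)
    }
  })
  res <- analyze_cohort(subjects, masks, config, verbose = verbose)

  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(res$cluster_table, "cluster_table.tsv")
  wt(res$posthoc_table, "posthoc_table.tsv")
  wt(res$roi_table, "roi_means.tsv")
  wt(res$cor_table, "neuropsych_correlations.tsv")
  wt(res$roc_table, "roc_table.tsv")
  wt(res$excluded, "excluded_subjects.tsv")
  write_map(res$anova$f_map, file.path(out_dir, "anova_F.nii.gz"))
  write_map(res$anova$p_map, file.path(out_dir, "anova_p.nii.gz"))
  write_map(res$conjunction$dmn_mask, file.path(out_dir, "dmn_mask.nii.gz"))
  meta <- list(
    n_subjects_input = nrow(manifest),
    n_subjects_retained = nrow(res$records),
    preprocess = unclass(config$preprocess),
    seeds = lapply(config$seeds, unclass),
    conjunction_q = config$conjunction_q,
    analysis_mask = config$analysis_mask,
    correction = unclass(res$correction),
    smoothness_fwhm_mm = res$smoothness_fwhm_mm,
    min_extent_k = res$correction$min_extent_k,
    n_clusters = length(res$clusters),
    roc_orientation = config$roc_orientation,
    master_seed = config$master_seed)
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
  invisible(res)
}
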