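#' Acquisition parameters
#'
#' Describes how a resting-state BOLD series was (or is to be) acquired:
#' repetition time, number of volumes, how many initial volumes are discarded
#' before analysis to allow longitudinal magnetization to reach steady state,
#' and the voxel size of the reconstruction grid.
#'
#' @param tr_seconds repetition time in seconds (> 0).
#' @param n_volumes total acquired volumes (> 0).
#' @param n_discard initial volumes to discard (>= 0, < `n_volumes`).
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(tr_seconds = 2, n_volumes = 250, n_discard = 10,
                       voxel_size_mm = c(3, 3, 3)) {
  dmn_assert(is.numeric(tr_seconds) && length(tr_seconds) == 1 && tr_seconds > 0,
             "bad_params", "tr_seconds must be a positive scalar")
  dmn_assert(n_volumes >= 1 && n_volumes == round(n_volumes),
             "bad_params", "n_volumes must be a positive integer")
  dmn_assert(n_discard >= 0 && n_discard == round(n_discard),
             "bad_params", "n_discard must be a non-negative integer")
  dmn_assert(n_discard < n_volumes,
             "bad_params", "n_discard must be smaller than n_volumes")
  dmn_assert(length(voxel_size_mm) == 3 && all(voxel_size_mm > 0),
             "bad_params", "voxel_size_mm must be 3 positive values")
  structure(list(tr_seconds = as.numeric(tr_seconds),
                 n_volumes = as.integer(n_volumes),
                 n_discard = as.integer(n_discard),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "acq_params")
}

#' 4-D BOLD series
#'
#' A subject's BOLD lattice indexed (i, j, k, t), with the affine mapping
#' 0-based voxel indices to MNI mm and its acquisition parameters. The
#' `discarded` flag records whether the initial dummy volumes have already
#' been dropped, so that preprocessing cannot be applied twice.
#'
#' @param data 4-D numeric array, time along the 4th dimension.
#' @param affine invertible 4x4 voxel-to-mm matrix.
#' @param params an [acq_params()] object.
#' @param discarded logical; have the initial volumes been removed already?
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine, params, discarded = FALSE) {
  dmn_assert(is.array(data) && length(dim(data)) == 4,
             "not_4d", "BOLD data must be a 4-D array")
  check_affine(affine)
  expected_t <- if (discarded) params$n_volumes - params$n_discard else
    params$n_volumes
  dmn_assert(dim(data)[4] == expected_t, "bad_params", sprintf(
    "time dimension (%d) does not match params (%d volumes expected)",
    dim(data)[4], expected_t))
  structure(list(data = data, affine = affine, params = params,
                 discarded = isTRUE(discarded)),
            class = "bold_series")
}

#' 3-D statistical or summary map
#'
#' A scalar lattice on the same grid as the BOLD series that produced it.
#' `kind` records what the values are: correlation (`r`), Fisher-transformed
#' correlation (`z`), test statistics (`t`, `F`), p values (`p`), or a plain
#' mean image (`mean`). Missing voxels are `NA`.
#'
#' @param data 3-D numeric array.
#' @param affine invertible 4x4 voxel-to-mm matrix.
#' @param kind one of `"r"`, `"z"`, `"t"`, `"F"`, `"p"`, `"mean"`.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(data, affine, kind = c("r", "z", "t", "F", "p", "mean")) {
  kind <- match.arg(kind)
  dmn_assert(is.array(data) && length(dim(data)) == 3,
             "not_3d", "map data must be a 3-D array")
  check_affine(affine)
  fin <- data[is.finite(data)]
  if (kind == "r")
    dmn_assert(all(fin >= -1 - 1e-9 & fin <= 1 + 1e-9), "bad_map_values",
               "kind='r' requires finite values in [-1, 1]")
  if (kind == "p")
    dmn_assert(all(fin >= 0 & fin <= 1 + 1e-12), "bad_map_values",
               "kind='p' requires finite values in [0, 1]")
  structure(list(data = data, affine = affine, kind = kind),
            class = "volume_map")
}

#' Binary mask on a volume grid
#'
#' @param data 3-D logical (or 0/1 numeric) array.
#' @param affine invertible 4x4 voxel-to-mm matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, affine) {
  dmn_assert(is.array(data) && length(dim(data)) == 3,
             "not_3d", "mask data must be a 3-D array")
  storage.mode(data) <- "logical"
  dmn_assert(!anyNA(data), "bad_mask", "mask may not contain NA")
  check_affine(affine)
  structure(list(data = data, affine = affine), class = "binary_mask")
}

#' Head-motion trace
#'
#' Per-volume rigid-body motion parameters as estimated by realignment:
#' three translations in mm and three rotations in degrees. Row count equals
#' the pre-discard volume count.
#'
#' @param translations_mm n x 3 numeric matrix of translations (mm).
#' @param rotations_deg n x 3 numeric matrix of rotations (degrees).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(translations_mm, rotations_deg) {
  translations_mm <- as.matrix(translations_mm)
  rotations_deg <- as.matrix(rotations_deg)
  dmn_assert(ncol(translations_mm) == 3 && ncol(rotations_deg) == 3,
             "bad_motion", "motion trace needs 3 translation and 3 rotation columns")
  dmn_assert(nrow(translations_mm) == nrow(rotations_deg),
             "bad_motion", "translation and rotation row counts differ")
  structure(list(translations_mm = translations_mm,
                 rotations_deg = rotations_deg),
            class = "motion_trace")
}

GROUP_LEVELS <- c("HC", "nonHE", "MHE", "cirrhotic-undiagnosed")

MANIFEST_COLUMNS <- c("subject_id", "group", "age_years", "gender",
                      "nct_a_seconds", "dst_score", "bold_path", "motion_path")

#' Read a 4-D BOLD NIfTI file
#'
#' @param path path to a NIfTI-1 `.nii`/`.nii.gz` file containing a 4-D
#'   series. TR is taken from the header (`pixdim[5]`, seconds assumed).
#' @param n_discard how many initial volumes the caller intends to discard;
#'   recorded in the returned parameters (default 0; the file itself is
#'   assumed undiscarded).
#' @return A [bold_series()].
#' @export
read_bold <- function(path, n_discard = 0) {
  dmn_assert(file.exists(path), "missing_file",
             sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  dmn_assert(length(d) == 4, "not_4d",
             sprintf("%s is not a 4-D series (found %d dims)", path, length(d)))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  check_affine(affine)
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else NA_real_
  dmn_assert(is.finite(tr), "bad_params",
             sprintf("%s: header does not carry a positive TR", path))
  params <- acq_params(tr_seconds = tr, n_volumes = d[4], n_discard = n_discard,
                       voxel_size_mm = affine_voxel_size(affine))
  bold_series(array(as.numeric(img), dim = d), affine, params,
              discarded = FALSE)
}

#' Write a BOLD series to NIfTI
#'
#' @param bold a [bold_series()].
#' @param path output `.nii`/`.nii.gz` path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path) {
  write_nifti_array(bold$data, bold$affine, path, tr = bold$params$tr_seconds)
}

#' Read / write 3-D maps and masks
#'
#' `write_map` stores the map as 32-bit float NIfTI (masks as 8-bit 0/1);
#' `read_map` restores it. Round trips are identity up to float32 rounding.
#'
#' @param map a [volume_map()] or (for `write_map`) a [binary_mask()].
#' @param path NIfTI file path.
#' @param kind map kind to attach on read (files do not record it).
#' @return `read_map` returns a [volume_map()]; `read_mask` a [binary_mask()].
#' @export
write_map <- function(map, path) {
  dmn_assert(inherits(map, "volume_map") || inherits(map, "binary_mask"),
             "bad_map", "write_map expects a volume_map or binary_mask")
  datatype <- if (inherits(map, "binary_mask")) "uint8" else "float"
  write_nifti_array(map$data * 1.0, map$affine, path, datatype = datatype)
}

#' @rdname write_map
#' @export
read_map <- function(path, kind = "mean") {
  dmn_assert(file.exists(path), "missing_file",
             sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  dmn_assert(length(d) == 3, "not_3d",
             sprintf("%s is not a 3-D volume", path))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  volume_map(array(as.numeric(img), dim = d), affine, kind)
}

#' @rdname write_map
#' @export
read_mask <- function(path) {
  m <- read_map(path, kind = "mean")
  binary_mask(m$data != 0, m$affine)
}

write_nifti_array <- function(data, affine, path, tr = NULL, datatype = "float") {
  dmn_assert(dir.exists(dirname(path)), "unwritable",
             sprintf("directory does not exist: %s", dirname(path)))
  img <- RNifti::asNifti(data)
  vs <- affine_voxel_size(affine)
  RNifti::pixdim(img) <- if (!is.null(tr) && length(dim(data)) == 4)
    c(vs, tr) else vs
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a delimited text table (TSV by default, CSV accepted) with
#' header columns `subject_id, group, age_years, gender, nct_a_seconds,
#' dst_score, bold_path, motion_path`. Group labels must be one of `HC`,
#' `nonHE`, `MHE`, `cirrhotic-undiagnosed`.
#'
#' @param path manifest file path.
#' @return A data.frame with one validated row per subject, in file order.
#' @export
read_manifest <- function(path) {
  dmn_assert(file.exists(path), "missing_file",
             sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  dmn_assert(length(missing) == 0, "bad_manifest",
             paste("manifest is missing column(s):",
                   paste(missing, collapse = ", ")))
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  dmn_assert(length(bad) == 0, "bad_manifest",
             paste("unknown group label(s):", paste(bad, collapse = ", ")))
  for (col in c("age_years", "nct_a_seconds", "dst_score")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    dmn_assert(!anyNA(v), "bad_manifest",
               sprintf("non-numeric value in column %s", col))
    df[[col]] <- v
  }
  dmn_assert(all(df$gender %in% c("M", "F")), "bad_manifest",
             "gender must be M or F")
  df[MANIFEST_COLUMNS]
}

#' @rdname read_manifest
#' @param manifest data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  dmn_assert(all(MANIFEST_COLUMNS %in% names(manifest)), "bad_manifest",
             "manifest is missing required columns")
  utils::write.table(manifest[MANIFEST_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motion-parameter file
#'
#' Whitespace-delimited text with six columns per volume: translations in mm
#' (x, y, z) then rotations in degrees (pitch, roll, yaw), one row per
#' acquired (pre-discard) volume.
#'
#' @param path motion file path.
#' @param n_volumes expected row count (the acquired volume count).
#' @return A [motion_trace()].
#' @export
read_motion <- function(path, n_volumes) {
  dmn_assert(file.exists(path), "missing_file",
             sprintf("file not found: %s", path))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dmn_assert(ncol(m) == 6, "bad_motion",
             sprintf("%s: expected 6 columns, found %d", path, ncol(m)))
  dmn_assert(nrow(m) == n_volumes, "bad_motion",
             sprintf("%s: expected %d rows, found %d", path, n_volumes, nrow(m)))
  dmn_assert(all(is.finite(m)), "bad_motion", "non-numeric motion values")
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' @rdname read_motion
#' @param trace a [motion_trace()].
#' @export
write_motion <- function(trace, path) {
  m <- cbind(trace$translations_mm, trace$rotations_deg)
  utils::write.table(m, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
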