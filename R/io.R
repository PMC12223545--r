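#' Read network time courses and motion parameters from TSV
#'
#' Expects a headerless (or headered) whitespace/tab-delimited table with one
#' row per time point and one column per network, plus an optional motion
#' table with six columns.
#'
#' @param tc_path Path to the time-course table.
#' @param motion_path Optional path to the motion-parameter table.
#' @param tr_seconds Repetition time in seconds.
#' @param header Whether the tables carry a header row (default FALSE).
#' @param ... Passed to [timecourse_set()].
#' @return A [timecourse_set()].
#' @export
read_timecourses_tsv <- function(tc_path, motion_path = NULL, tr_seconds,
                                 header = FALSE, ...) {
  tc <- as.matrix(read.table(tc_path, header = header, sep = "\t"))
  motion <- if (!is.null(motion_path)) {
    as.matrix(read.table(motion_path, header = header, sep = "\t"))
  }
  timecourse_set(tc, tr_seconds = tr_seconds, motion = motion, ...)
}

#' Read / write a demographics and scores table
#'
#' The table is tab-delimited with columns `subject_id`, `sex`,
#' `age_months_t0`, `age_months_t2`, `site` and optionally `delta_psych`,
#' `delta_cog`.
#'
#' @param path File path.
#' @param cohort A `synthetic_cohort` (for writing).
#' @return `read_demographics_tsv` returns a data frame.
#' @export
read_demographics_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_demographics_tsv
#' @export
write_demographics_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  df <- cohort$demographics
  df$delta_psych <- cohort$delta_psych
  df$delta_cog <- cohort$delta_cog
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read fusion loadings as TSV
#'
#' One table per modality: subjects x k with a header `comp_1 ... comp_k`
#' and subject IDs in the first column when available.
#'
#' @param result A [fusion_result()].
#' @param path Output path (single modality) — see `modality`.
#' @param modality Which modality's loadings to write.
#' @return The path, invisibly; `read_loadings_tsv` returns a matrix.
#' @export
write_loadings_tsv <- function(result, path, modality = names(result$loadings)[1L]) {
  A <- result$loadings[[modality]]
  stopifnot(!is.null(A))
  df <- data.frame(subject_id = rownames(A) %||% sprintf("sub-%04d", seq_len(nrow(A))),
                   A, stringsAsFactors = FALSE)
  names(df) <- c("subject_id", sprintf("comp_%d", seq_len(ncol(A))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loadings_tsv
#' @export
read_loadings_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  A <- as.matrix(df[, -1L, drop = FALSE])
  rownames(A) <- df[[1L]]
  A
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export FNC source rows as devectorized matrices
#'
#' Writes each source row of the FNC modality as an `n x n` symmetric
#' matrix in TSV form (`<prefix>_comp<j>.tsv`).
#'
#' @param result A [fusion_result()] with an `fnc` source matrix.
#' @param n_networks Matrix dimension (e.g., 53).
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_fnc_sources_tsv <- function(result, n_networks, prefix) {
  S <- result$sources$fnc
  stopifnot(!is.null(S))
  paths <- character(nrow(S))
  for (j in seq_len(nrow(S))) {
    m <- fnc_devectorize(S[j, ], n_networks, diag_value = 0)
    paths[j] <- sprintf("%s_comp%d.tsv", prefix, j)
    write.table(m, paths[j], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Place masked-vector values into a volume
#'
#' @param values Numeric vector with one entry per in-mask voxel (mask
#'   voxels enumerated in R's column-major array order).
#' @param mask Logical 3D array.
#' @param fill Out-of-mask fill value (default 0).
#' @return Numeric 3D array of `dim(mask)`.
#' @export
mask_to_volume <- function(values, mask, fill = 0) {
  stopifnot(sum(mask) == length(values))
  vol <- array(fill, dim(mask))
  vol[mask] <- values
  vol
}

#' Write source maps or coupling maps as NIfTI volumes
#'
#' `write_gmv_sources_nifti` writes each GMV source row as one volume;
#' `write_coupling_nifti` writes the r, q and significance volumes of a
#' [voxelwise_coupling()] map.
#'
#' @param result A [fusion_result()] with a `gmv` source matrix.
#' @param map A `coupling_map`.
#' @param mask Logical 3D array matching the masked feature order.
#' @param prefix Output path prefix (files get `.nii.gz` suffixes).
#' @return Character vector of written paths, invisibly.
#' @export
write_gmv_sources_nifti <- function(result, mask, prefix) {
  S <- result$sources$gmv
  stopifnot(!is.null(S))
  paths <- character(nrow(S))
  for (j in seq_len(nrow(S))) {
    paths[j] <- sprintf("%s_comp%d.nii.gz", prefix, j)
    RNifti::writeNifti(RNifti::asNifti(mask_to_volume(S[j, ], mask)), paths[j])
  }
  invisible(paths)
}

#' @rdname write_gmv_sources_nifti
#' @export
write_coupling_nifti <- function(map, mask, prefix) {
  stopifnot(inherits(map, "coupling_map"))
  vols <- list(r = map$r, q = map$q, sig = as.numeric(map$sig_mask))
  paths <- character(0)
  for (nm in names(vols)) {
    v <- vols[[nm]]
    v[is.na(v)] <- if (nm == "q") 1 else 0
    p <- sprintf("%s_%s.nii.gz", prefix, nm)
    RNifti::writeNifti(RNifti::asNifti(mask_to_volume(v, mask)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a JSON provenance sidecar
#'
#' Records the configuration, seed, package version and any convergence
#' metadata next to a numeric artifact so the artifact can be regenerated
#' from the sidecar alone.
#'
#' @param path Output `.json` path.
#' @param config Named list of configuration values.
#' @param seed Integer seed.
#' @param extra Optional named list (e.g., convergence info).
#' @return The path, invisibly.
#' @export
write_sidecar_json <- function(path, config = list(), seed = NA_integer_,
                               extra = list()) {
  payload <- list(
    package = "longfuse",
    version = as.character(packageVersion("longfuse")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    extra = extra,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Serialize a cohort or delta matrix to an array container
#'
#' Matrices are stored in R's native serialization (`.rds`), the package's
#' binary array container; demographics travel as TSV via
#' [write_demographics_tsv()].
#'
#' @param x Object to store.
#' @param path Output `.rds` path.
#' @return The path, invisibly; `read_array` returns the object.
#' @export
write_array <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_array
#' @export
read_array <- function(path) readRDS(path)
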