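#' Construct a time-course set
#'
#' Bundles one scan's network time courses with its repetition time and
#' motion parameters.
#'
#' @param tc `T x n_networks` numeric matrix of network time courses.
#' @param tr_seconds Positive repetition time in seconds.
#' @param motion Optional `T x 6` matrix of rigid-body motion parameters
#'   (3 rotations, 3 translations).
#' @param subject_id,timepoint Identifiers; `timepoint` is `"baseline"` or
#'   `"year2"`.
#' @return An object of class `timecourse_set`.
#' @export
timecourse_set <- function(tc, tr_seconds, motion = NULL,
                           subject_id = NA_character_,
                           timepoint = c("baseline", "year2")) {
  tc <- as.matrix(tc)
  timepoint <- match.arg(timepoint)
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    lf_stop("tr_seconds must be positive", "longfuse_config_error")
  }
  if (nrow(tc) <= 20L) {
    lf_stop("time courses must have more than 20 time points",
            "longfuse_config_error")
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nrow(tc)) {
      lf_stop("motion must have one row per time point",
              "longfuse_config_error")
    }
  }
  structure(list(tc = tc, tr_seconds = tr_seconds, motion = motion,
                 subject_id = subject_id, timepoint = timepoint),
            class = "timecourse_set")
}

# zero-phase Butterworth bandpass of one column
lf_bandpass <- function(x, tr_seconds, band, order) {
  nyq <- 1 / (2 * tr_seconds)
  wn <- band / nyq
  if (any(wn <= 0) || any(wn >= 1)) {
    lf_stop(sprintf(
      "band (%.3g, %.3g) Hz is outside (0, Nyquist = %.3g) Hz",
      band[1], band[2], nyq), "longfuse_config_error")
  }
  bf <- signal::butter(order, wn, type = "pass")
  signal::filtfilt(bf, x)
}

#' Post-process network time courses
#'
#' Applies, in order: (1) removal of linear, quadratic and cubic polynomial
#' trends; (2) despiking, replacing samples whose robust z-score (relative to
#' median and MAD of the detrended series) exceeds `outlier_z` by spline
#' interpolation of the remaining samples; (3) regression of the six motion
#' parameters and their backward first differences; (4) zero-phase Butterworth
#' bandpass filtering, 0.01-0.15 Hz by default.
#'
#' @param x A [timecourse_set()].
#' @param detrend_degree Polynomial detrending degree (default 3).
#' @param outlier_z Robust z-score threshold for despiking (default 3).
#' @param motion_derivatives Include first differences of the motion
#'   parameters as regressors (default TRUE).
#' @param band Length-2 passband in Hz.
#' @param filter_order Butterworth order per pass (default 5; applied
#'   forward-backward, so the effective attenuation is doubled).
#' @return A `timecourse_set` with processed time courses.
#' @export
postprocess_timecourses <- function(x, detrend_degree = 3L, outlier_z = 3,
                                    motion_derivatives = TRUE,
                                    band = c(0.01, 0.15), filter_order = 5L) {
  stopifnot(inherits(x, "timecourse_set"))
  tc <- x$tc
  n_t <- nrow(tc)
  min_t <- 3L * (2L * filter_order + 1L)
  if (n_t < min_t) {
    lf_stop(sprintf(
      "need at least %d time points for a stable order-%d bandpass; got %d",
      min_t, filter_order, n_t), "longfuse_config_error")
  }
  t_idx <- seq_len(n_t)
  # 1) polynomial detrend (includes mean removal)
  P <- cbind(1, stats::poly(t_idx, degree = detrend_degree))
  tc <- tc - P %*% qr.solve(P, tc)
  # 2) robust despiking
  for (j in seq_len(ncol(tc))) {
    v <- tc[, j]
    s <- mad(v)
    if (s == 0) next
    bad <- abs(v - median(v)) / s > outlier_z
    if (any(bad) && sum(!bad) >= 4L) {
      tc[bad, j] <- spline(t_idx[!bad], v[!bad], xout = t_idx[bad],
                           method = "natural")$y
    }
  }
  # 3) motion regression (parameters + backward differences); the
  # regressors are detrended with the same polynomial basis as the data so
  # that trend removal and motion removal commute
  if (!is.null(x$motion)) {
    M <- x$motion
    if (motion_derivatives) M <- cbind(M, rbind(0, diff(M)))
    M <- M - P %*% qr.solve(P, M)
    M <- cbind(1, M)
    tc <- tc - M %*% qr.solve(M, tc)
  }
  # 4) zero-phase bandpass
  tc <- apply(tc, 2L, lf_bandpass, tr_seconds = x$tr_seconds,
              band = band, order = filter_order)
  out <- x
  out$tc <- tc
  out
}

#' Compute a static FNC matrix
#'
#' Pearson correlation between all pairs of (post-processed) network time
#' courses. Zero-variance networks are flagged: their rows/columns are set to
#' `NA` and listed in the `bad_networks` attribute.
#'
#' @param x A [timecourse_set()] or a `T x n` numeric matrix.
#' @return An `n x n` symmetric correlation matrix of class `fnc_matrix`
#'   with unit diagonal.
#' @export
compute_fnc <- function(x) {
  tc <- if (inherits(x, "timecourse_set")) x$tc else as.matrix(x)
  sds <- apply(tc, 2L, sd)
  bad <- which(sds == 0 | !is.finite(sds))
  fnc <- suppressWarnings(cor(tc))
  diag(fnc) <- 1
  if (length(bad)) {
    fnc[bad, ] <- NA_real_
    fnc[, bad] <- NA_real_
    diag(fnc)[bad] <- 1
    warning(sprintf("zero-variance networks flagged: %s",
                    paste(bad, collapse = ", ")))
  }
  structure(fnc, class = c("fnc_matrix", "matrix", "array"),
            bad_networks = bad)
}

#' Vectorize / restore an FNC matrix
#'
#' `fnc_vectorize` extracts the row-major upper triangle (diagonal excluded)
#' of a symmetric matrix; `fnc_devectorize` restores the symmetric matrix
#' with the given diagonal. They are mutual inverses off the diagonal.
#'
#' @param m Symmetric numeric matrix.
#' @param v Numeric vector of length `n(n-1)/2`.
#' @param n Matrix dimension.
#' @param diag_value Diagonal to use when restoring (default 1).
#' @return A vector of length `n(n-1)/2`, or an `n x n` symmetric matrix.
#' @export
fnc_vectorize <- function(m) {
  m <- unclass(m)
  if (nrow(m) != ncol(m) ||
      max(abs(m - t(m)), na.rm = TRUE) > 1e-8) {
    lf_stop("m must be a symmetric square matrix", "longfuse_config_error")
  }
  # column-major lower triangle of a symmetric matrix enumerates the
  # row-major upper triangle
  m[lower.tri(m)]
}

#' @rdname fnc_vectorize
#' @export
fnc_devectorize <- function(v, n, diag_value = 1) {
  if (length(v) != n * (n - 1L) / 2L) {
    lf_stop(sprintf("length(v) = %d but n(n-1)/2 = %d",
                    length(v), n * (n - 1L) / 2L), "longfuse_config_error")
  }
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Evaluate mask-agreement quality control
#'
#' Given per-scan 3D brain masks on a common grid, builds the group mask
#' (voxels present in more than `agreement` of the scans) and correlates each
#' individual mask with it over the top 10 axial slices, the bottom 10 axial
#' slices and the whole volume. A scan passes when the three correlations
#' exceed the respective thresholds (defaults 0.75 / 0.55 / 0.8).
#'
#' @param masks List of logical 3D arrays sharing one grid, with at least 20
#'   axial (third-dimension) slices.
#' @param thresholds Named numeric vector `c(top, bottom, whole)`.
#' @param agreement Group-mask agreement fraction (default 0.9).
#' @return A data frame of class `qc_report` with columns `scan`, `r_top10`,
#'   `r_bottom10`, `r_whole`, `passed`; the group mask is in attribute
#'   `group_mask`.
#' @export
qc_masks <- function(masks, thresholds = c(top = 0.75, bottom = 0.55,
                                           whole = 0.8), agreement = 0.9) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  dims <- dim(masks[[1L]])
  if (length(dims) != 3L) lf_stop("masks must be 3D arrays",
                                  "longfuse_config_error")
  for (m in masks) {
    if (!identical(dim(m), dims)) {
      lf_stop("all masks must share one grid", "longfuse_config_error")
    }
  }
  if (dims[3L] < 20L) {
    lf_stop("need at least 20 axial slices to define top/bottom-10 slices",
            "longfuse_config_error")
  }
  cube <- array(unlist(masks), dim = c(dims, length(masks)))
  group <- apply(cube, 1:3, mean) > agreement
  nz <- dims[3L]
  top_idx <- (nz - 9L):nz
  bot_idx <- 1:10
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    r_top <- suppressWarnings(cor(as.numeric(m[, , top_idx]),
                                  as.numeric(group[, , top_idx])))
    r_bot <- suppressWarnings(cor(as.numeric(m[, , bot_idx]),
                                  as.numeric(group[, , bot_idx])))
    r_all <- suppressWarnings(cor(as.numeric(m), as.numeric(group)))
    qc_report(r_top, r_bot, r_all, thresholds, scan = i)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_mask") <- group
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Build a QC report row from precomputed correlations
#'
#' @param r_top10,r_bottom10,r_whole Mask-agreement correlations.
#' @param thresholds Named numeric vector `c(top, bottom, whole)`.
#' @param scan Scan identifier.
#' @return One-row data frame with the pass decision
#'   (`r_top10 > top & r_bottom10 > bottom & r_whole > whole`).
#' @export
qc_report <- function(r_top10, r_bottom10, r_whole,
                      thresholds = c(top = 0.75, bottom = 0.55, whole = 0.8),
                      scan = NA_integer_) {
  passed <- isTRUE(r_top10 > thresholds[["top"]] &&
                   r_bottom10 > thresholds[["bottom"]] &&
                   r_whole > thresholds[["whole"]])
  data.frame(scan = scan, r_top10 = r_top10, r_bottom10 = r_bottom10,
             r_whole = r_whole, passed = passed)
}

#' Individual brain mask from a first volume
#'
#' Voxels exceeding 90% of the whole-volume mean signal are set to TRUE.
#'
#' @param vol Numeric 3D array (first fMRI time volume).
#' @param frac Fraction of the mean signal (default 0.9).
#' @return Logical array of the same shape.
#' @export
individual_mask <- function(vol, frac = 0.9) {
  vol > frac * mean(vol)
}

#' Build a longitudinal change matrix
#'
#' Subject-wise difference `baseline - followup` of per-subject feature rows.
#' Subjects missing either timepoint are excluded (and reported via a
#' message). With this sign convention a negative one-sample T on the fused
#' loadings reads as an increase of the change pattern with age.
#'
#' @param baseline,followup Numeric matrices with subject IDs as row names
#'   and identical feature spaces.
#' @param feature_space `"fnc_cells"` or `"gmv_voxels"`.
#' @param feature_index Optional feature coordinate table (cells or voxels).
#' @return An object of class `delta_matrix` with elements `data`,
#'   `feature_space`, `feature_index`, `subject_ids`.
#' @export
build_delta <- function(baseline, followup,
                        feature_space = c("fnc_cells", "gmv_voxels"),
                        feature_index = NULL) {
  feature_space <- match.arg(feature_space)
  baseline <- as.matrix(baseline)
  followup <- as.matrix(followup)
  if (ncol(baseline) != ncol(followup)) {
    lf_stop("feature spaces of the two timepoints differ",
            "longfuse_config_error")
  }
  if (is.null(rownames(baseline))) {
    rownames(baseline) <- sprintf("sub-%04d", seq_len(nrow(baseline)))
  }
  if (is.null(rownames(followup))) {
    rownames(followup) <- sprintf("sub-%04d", seq_len(nrow(followup)))
  }
  common <- intersect(rownames(baseline), rownames(followup))
  if (length(common) == 0L) {
    lf_stop("no subjects present at both timepoints", "longfuse_config_error")
  }
  dropped <- setdiff(union(rownames(baseline), rownames(followup)), common)
  if (length(dropped)) {
    message(sprintf("build_delta: excluded %d subject(s) missing a timepoint",
                    length(dropped)))
  }
  d <- baseline[common, , drop = FALSE] - followup[common, , drop = FALSE]
  structure(list(data = d, feature_space = feature_space,
                 feature_index = feature_index, subject_ids = common,
                 dropped = dropped),
            class = "delta_matrix")
}

# internal: accept a delta_matrix or a plain matrix
lf_delta_data <- function(x) {
  if (inherits(x, "delta_matrix")) x$data else as.matrix(x)
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("delta_matrix (%s): %d subjects x %d features\n",
              x$feature_space, nrow(x$data), ncol(x$data)))
  invisible(x)
}
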