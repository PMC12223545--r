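#' Asymmetric fusion pipeline
#'
#' Infomax ICA of the delta-FNC matrix followed by voxel-wise coupling maps
#' between every functional loading column and the raw delta-GMV data, plus
#' loading-level one-sample t statistics.
#'
#' @param delta_fnc,delta_gmv `delta_matrix` objects or matrices over the
#'   same subjects.
#' @param k Number of components (default 5).
#' @param seed Integer seed.
#' @param q_threshold FDR level for the coupling maps (default 0.05).
#' @param ... Passed to [infomax_ica()].
#' @return List with `ica` (a [fusion_result()]), `coupling` (list of
#'   [voxelwise_coupling()] maps, one per component), `loading_stats`.
#' @export
fuse_asym <- function(delta_fnc, delta_gmv, k = 5L, seed = 1L,
                      q_threshold = 0.05, ...) {
  XF <- lf_delta_data(delta_fnc)
  XG <- lf_delta_data(delta_gmv)
  if (nrow(XF) != nrow(XG)) {
    lf_stop("modalities have different subject counts", "longfuse_config_error")
  }
  ica <- infomax_ica(XF, k = k, seed = seed, modality = "fnc", ...)
  A <- ica$loadings$fnc
  coupling <- lapply(seq_len(k), function(j) {
    voxelwise_coupling(A[, j], XG, q_threshold, component_index = j)
  })
  list(ica = ica, coupling = coupling, loading_stats = loading_tests(ica))
}

#' Symmetric fusion pipeline
#'
#' mCCA + joint ICA of the two change matrices plus loading-level one-sample
#' t statistics corrected jointly across both modalities.
#'
#' @inheritParams fuse_asym
#' @return List with `fusion` (a [fusion_result()]) and `loading_stats`.
#' @export
fuse_sym <- function(delta_fnc, delta_gmv, k = 5L, seed = 1L, ...) {
  fit <- mcca_jica(delta_fnc, delta_gmv, k = k, seed = seed, ...)
  list(fusion = fit, loading_stats = loading_tests(fit))
}

#' Run the sex and score-quartile contrasts of a cohort analysis
#'
#' @param asym Result of [fuse_asym()] (or NULL to skip the voxel-wise
#'   contrasts).
#' @param sym Result of [fuse_sym()] (or NULL to skip the loading-pair
#'   contrast).
#' @param delta_gmv Delta-GMV matrix used by the asymmetric contrasts.
#' @param sex Per-subject sex labels.
#' @param scores Named list of score vectors (e.g.,
#'   `list(delta_psych = ..., delta_cog = ...)`).
#' @param q_gender,q_quartile FDR levels (defaults 0.001 and 0.05).
#' @return Nested list of contrasts.
#' @export
run_contrasts <- function(asym = NULL, sym = NULL, delta_gmv = NULL, sex,
                          scores = list(), q_gender = 0.001,
                          q_quartile = 0.05) {
  out <- list()
  if (!is.null(asym) && !is.null(delta_gmv)) {
    A <- asym$ica$loadings$fnc
    out$gender_asym <- lapply(seq_len(ncol(A)), function(j) {
      gender_contrast_asym(A[, j], delta_gmv, sex, q_gender)
    })
    out$quartile <- lapply(names(scores), function(nm) {
      lapply(seq_len(ncol(A)), function(j) {
        quartile_contrast(A[, j], delta_gmv, scores[[nm]], q_quartile,
                          score_name = nm)
      })
    })
    names(out$quartile) <- names(scores)
  }
  if (!is.null(sym)) {
    out$gender_sym <- gender_contrast_sym(sym$fusion, sex, q_gender)
  }
  out
}
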