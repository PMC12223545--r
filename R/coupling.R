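# internal: vectorized Pearson correlation of one vector against matrix
# columns, with two-sided p from the t distribution; constant columns -> NA
lf_cor_map <- function(x, G) {
  n <- length(x)
  xs <- x - mean(x)
  xn <- sqrt(sum(xs^2))
  mu <- colMeans(G)
  Gc <- sweep(G, 2L, mu)
  gn <- sqrt(colSums(Gc^2))
  bad <- gn == 0 | !is.finite(gn)
  r <- as.vector(crossprod(xs, Gc)) / (xn * gn)
  r[bad] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n, n_constant = sum(bad))
}

#' Voxel-wise structure-function coupling map
#'
#' Pearson correlation between one loading column (typically a functional
#' change-pattern loading) and every voxel of the raw delta-GMV matrix, with
#' two-sided p-values and BH-FDR correction across all in-mask voxels.
#' Constant voxels are excluded from the FDR family and reported.
#'
#' @param loadings_col Numeric subject vector (length >= 10).
#' @param delta_gmv `delta_matrix` or `n x n_voxels` matrix, subjects
#'   aligned with `loadings_col`.
#' @param q_threshold FDR level for the significance mask (default 0.05).
#' @param component_index Optional component label carried into the result.
#' @return An object of class `coupling_map` with `r`, `p`, `q`, `sig_mask`,
#'   `n_subjects_used`, `q_threshold`, `component_index`.
#' @export
voxelwise_coupling <- function(loadings_col, delta_gmv, q_threshold = 0.05,
                               component_index = NA_integer_) {
  G <- lf_delta_data(delta_gmv)
  x <- as.numeric(loadings_col)
  if (length(x) != nrow(G)) {
    lf_stop("loadings and delta_gmv subject counts differ",
            "longfuse_config_error")
  }
  if (length(x) < 10L) lf_stop("need at least 10 subjects",
                               "longfuse_config_error")
  lf_check_prob(q_threshold, "q_threshold")
  cm <- lf_cor_map(x, G)
  if (cm$n_constant > 0) {
    message(sprintf("voxelwise_coupling: %d constant voxel(s) excluded",
                    cm$n_constant))
  }
  adj <- bh_fdr(cm$p, q_threshold)
  structure(list(component_index = component_index, r = cm$r, p = cm$p,
                 q = adj$q, sig_mask = adj$reject,
                 n_subjects_used = cm$n, q_threshold = q_threshold),
            class = "coupling_map")
}

#' @export
print.coupling_map <- function(x, ...) {
  cat(sprintf(
    "coupling_map (component %s): %d voxels, %d significant at q < %g (n = %d)\n",
    x$component_index, length(x$r), sum(x$sig_mask, na.rm = TRUE),
    x$q_threshold, x$n_subjects_used))
  invisible(x)
}

#' Sex contrast of voxel-wise coupling (asymmetric arm)
#'
#' Computes the per-sex voxel-wise correlation maps between a loading column
#' and delta-GMV, their female-minus-male difference, and a per-voxel Fisher
#' z two-independent-sample test of the correlation difference with BH-FDR
#' across voxels (default level 0.001).
#'
#' @param loadings_col Numeric subject vector.
#' @param delta_gmv `delta_matrix` or matrix aligned with `loadings_col`.
#' @param sex Character/factor with levels "F" and "M".
#' @param q_threshold FDR level (default 0.001).
#' @param use_adjusted Compare the FDR-adjusted q (default) rather than the
#'   raw p against `q_threshold`.
#' @return An object of class `group_coupling_contrast` with per-group maps
#'   (`map_a` = female, `map_b` = male), `difference` (r_F - r_M), `z`, `p`,
#'   `q`, `sig_mask` and group sizes.
#' @export
gender_contrast_asym <- function(loadings_col, delta_gmv, sex,
                                 q_threshold = 0.001, use_adjusted = TRUE) {
  G <- lf_delta_data(delta_gmv)
  x <- as.numeric(loadings_col)
  sex <- as.character(sex)
  stopifnot(length(sex) == length(x), length(x) == nrow(G))
  i_f <- sex == "F"; i_m <- sex == "M"
  if (sum(i_f) < 10L || sum(i_m) < 10L) {
    lf_stop("each sex group needs at least 10 subjects",
            "longfuse_config_error")
  }
  map_f <- lf_cor_map(x[i_f], G[i_f, , drop = FALSE])
  map_m <- lf_cor_map(x[i_m], G[i_m, , drop = FALSE])
  ft <- fisher_z_test(map_f$r, map_f$n, map_m$r, map_m$n)
  adj <- bh_fdr(ft$p, q_threshold)
  crit <- if (use_adjusted) adj$q else ft$p
  structure(list(map_a = map_f, map_b = map_m, groups = c("F", "M"),
                 n = c(F = map_f$n, M = map_m$n),
                 difference = map_f$r - map_m$r, z = ft$z, p = ft$p,
                 q = adj$q,
                 sig_mask = !is.na(crit) & crit < q_threshold,
                 q_threshold = q_threshold),
            class = "group_coupling_contrast")
}

#' Sex contrast of loading-loading coupling (symmetric arm)
#'
#' For every pair (i, j) of structural component i and functional component
#' j, correlates the GMV loading column i with the FNC loading column j
#' separately within female and within male subjects, takes the
#' female-minus-male difference, and tests each pair with the Fisher z
#' two-sample test, BH-FDR corrected across the k x k pairs.
#'
#' @param result A [fusion_result()] with `fnc` and `gmv` loadings.
#' @param sex Character/factor with levels "F" and "M", one per subject.
#' @param q_threshold FDR level (default 0.001).
#' @return An object of class `group_coupling_contrast` whose `difference`,
#'   `z`, `p`, `q` and `sig_mask` are `k x k` matrices (rows = GMV
#'   components, columns = FNC components); `r_f` and `r_m` hold the
#'   per-sex correlation grids.
#' @export
gender_contrast_sym <- function(result, sex, q_threshold = 0.001) {
  stopifnot(inherits(result, "fusion_result"))
  A_F <- result$loadings$fnc
  A_G <- result$loadings$gmv
  if (is.null(A_F) || is.null(A_G)) {
    lf_stop("result must carry both fnc and gmv loadings",
            "longfuse_config_error")
  }
  sex <- as.character(sex)
  stopifnot(length(sex) == nrow(A_F))
  i_f <- sex == "F"; i_m <- sex == "M"
  if (sum(i_f) < 10L || sum(i_m) < 10L) {
    lf_stop("each sex group needs at least 10 subjects",
            "longfuse_config_error")
  }
  r_f <- cor(A_G[i_f, , drop = FALSE], A_F[i_f, , drop = FALSE])
  r_m <- cor(A_G[i_m, , drop = FALSE], A_F[i_m, , drop = FALSE])
  ft <- fisher_z_test(r_f, sum(i_f), r_m, sum(i_m))
  adj <- bh_fdr(as.vector(ft$p), q_threshold)
  k <- result$k
  structure(list(r_f = r_f, r_m = r_m, groups = c("F", "M"),
                 n = c(F = sum(i_f), M = sum(i_m)),
                 difference = r_f - r_m, z = ft$z,
                 p = matrix(ft$p, k, k),
                 q = matrix(adj$q, k, k),
                 dz_lo = ft$dz_lo, dz_hi = ft$dz_hi,
                 sig_mask = matrix(adj$reject, k, k),
                 q_threshold = q_threshold),
            class = "group_coupling_contrast")
}

#' @export
print.group_coupling_contrast <- function(x, ...) {
  cat(sprintf(
    "group_coupling_contrast (%s - %s): %d element(s) significant at q < %g\n",
    x$groups[1], x$groups[2], sum(x$sig_mask, na.rm = TRUE), x$q_threshold))
  invisible(x)
}

#' Score-quartile contrast of voxel-wise coupling
#'
#' Splits subjects by the quartiles of a change score (lower group: scores
#' at or below the first quartile; upper group: scores at or above the third
#' quartile, quartiles by linear interpolation), computes each group's
#' voxel-wise coupling map, and reports the upper-minus-lower difference with
#' a per-voxel Fisher z test, BH-FDR corrected.
#'
#' @param loadings_col Numeric subject vector.
#' @param delta_gmv `delta_matrix` or matrix aligned with `loadings_col`.
#' @param scores Numeric change scores, one per subject (>= 40 non-missing).
#' @param q_threshold FDR level (default 0.05).
#' @param score_name Label, e.g. `"delta_psych"` or `"delta_cog"`.
#' @return An object of class `quartile_contrast` with `upper_map`,
#'   `lower_map` ([voxelwise_coupling()] results), `difference`
#'   (r_upper - r_lower), `z`, `p`, `q`, `sig_mask`.
#' @export
quartile_contrast <- function(loadings_col, delta_gmv, scores,
                              q_threshold = 0.05,
                              score_name = "delta_score") {
  G <- lf_delta_data(delta_gmv)
  x <- as.numeric(loadings_col)
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(x), length(x) == nrow(G))
  ok <- !is.na(scores)
  if (sum(ok) < 40L) {
    lf_stop("need scores for at least 40 subjects", "longfuse_config_error")
  }
  q1 <- quantile(scores[ok], 0.25, type = 7, names = FALSE)
  q3 <- quantile(scores[ok], 0.75, type = 7, names = FALSE)
  if (q1 == q3) {
    lf_stop("degenerate score distribution: quartiles coincide",
            "longfuse_config_error")
  }
  lower <- ok & scores <= q1
  upper <- ok & scores >= q3
  lower_map <- voxelwise_coupling(x[lower], G[lower, , drop = FALSE],
                                  q_threshold)
  upper_map <- voxelwise_coupling(x[upper], G[upper, , drop = FALSE],
                                  q_threshold)
  ft <- fisher_z_test(upper_map$r, sum(upper), lower_map$r, sum(lower))
  adj <- bh_fdr(ft$p, q_threshold)
  structure(list(score_name = score_name, upper_map = upper_map,
                 lower_map = lower_map,
                 n = c(upper = sum(upper), lower = sum(lower)),
                 difference = upper_map$r - lower_map$r,
                 z = ft$z, p = ft$p, q = adj$q, sig_mask = adj$reject,
                 q_threshold = q_threshold),
            class = "quartile_contrast")
}

#' @export
print.quartile_contrast <- function(x, ...) {
  cat(sprintf(
    "quartile_contrast (%s): upper n = %d, lower n = %d, %d voxel(s) significant at q < %g\n",
    x$score_name, x$n[["upper"]], x$n[["lower"]],
    sum(x$sig_mask, na.rm = TRUE), x$q_threshold))
  invisible(x)
}
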