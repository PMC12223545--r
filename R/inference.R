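#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with a rejection mask at
#' the requested level. Missing values are excluded from the family and stay
#' `NA` in the output. Rejection is strict (`q_adjusted < level`), matching
#' the significance-mask convention used throughout the package.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param level FDR level in (0, 1), default 0.05.
#' @return List with `q` (adjusted values), `reject` (logical mask) and
#'   `level`.
#' @export
bh_fdr <- function(p, level = 0.05) {
  lf_check_prob(level, "level")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    lf_stop("p-values must lie in [0, 1]", "longfuse_config_error")
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  list(q = q, reject = !is.na(q) & q < level, level = level)
}

# direction label under the baseline-minus-followup sign convention:
# a negative T means the change pattern's expression grows with age
lf_direction <- function(statistic, q, level) {
  ifelse(is.na(q) | q >= level, "n.s.",
         ifelse(statistic < 0, "increase-with-age", "decrease-with-age"))
}

#' One-sample t-test on a loading column
#'
#' Classical one-sample t-test of the loadings against zero. Under the
#' baseline-minus-followup convention of [build_delta()], a significant
#' negative T is labelled `"increase-with-age"` and a significant positive T
#' `"decrease-with-age"`; labels require the FDR-adjusted q (see
#' [loading_tests()]) and are `"n.s."` when `q` is absent.
#'
#' @param x Numeric vector (one loading column), length >= 3, nonzero
#'   variance.
#' @return Data frame with `statistic`, `dof`, `p`, `q` (NA here), and
#'   `direction`.
#' @export
one_sample_t <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) lf_stop("need at least 3 observations",
                              "longfuse_config_error")
  if (sd(x) == 0) lf_stop("zero variance", "longfuse_config_error")
  tt <- t.test(x, mu = 0)
  data.frame(statistic = unname(tt$statistic), dof = unname(tt$parameter),
             p = tt$p.value, q = NA_real_, direction = "n.s.",
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test split by a two-level factor
#'
#' @param x Numeric vector.
#' @param labels Two-level factor/character of the same length; the
#'   statistic is `mean(level1) - mean(level2)` scaled, so swapping levels
#'   negates T.
#' @return Data frame with `statistic`, `dof`, `p`, the group levels and
#'   sizes.
#' @export
two_sample_t_by_group <- function(x, labels) {
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  if (length(lv) != 2L) {
    lf_stop("labels must have exactly two observed levels",
            "longfuse_config_error")
  }
  g1 <- x[labels == lv[1L]]; g2 <- x[labels == lv[2L]]
  if (length(g1) < 2L || length(g2) < 2L) {
    lf_stop("both groups need at least 2 observations",
            "longfuse_config_error")
  }
  tt <- t.test(g1, g2, var.equal = FALSE)
  data.frame(statistic = unname(tt$statistic), dof = unname(tt$parameter),
             p = tt$p.value, group1 = lv[1L], group2 = lv[2L],
             n1 = length(g1), n2 = length(g2), stringsAsFactors = FALSE)
}

#' Loading-level significance table for a fusion result
#'
#' One-sample t-tests of every loading column of every modality against
#' zero, with BH-FDR correction applied jointly across all modalities and
#' components, and age-direction labels under the baseline-minus-followup
#' convention.
#'
#' @param result A [fusion_result()].
#' @param level FDR level (default 0.05).
#' @return Data frame with columns `modality`, `component`, `statistic`,
#'   `dof`, `p`, `q`, `direction`.
#' @export
loading_tests <- function(result, level = 0.05) {
  stopifnot(inherits(result, "fusion_result"))
  rows <- list()
  for (m in names(result$loadings)) {
    A <- result$loadings[[m]]
    for (j in seq_len(ncol(A))) {
      r <- one_sample_t(A[, j])
      r$modality <- m; r$component <- j
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p, level)
  out$q <- adj$q
  out$direction <- lf_direction(out$statistic, out$q, level)
  out[, c("modality", "component", "statistic", "dof", "p", "q", "direction")]
}

#' Remove site effects from loading columns
#'
#' Least-squares residualization of each loading column on site indicator
#' variables; residual per-site means are numerically zero. Sites with a
#' single subject are dropped with a warning.
#'
#' @param loadings `n x k` numeric matrix.
#' @param site Factor/character of site labels, length `n`.
#' @return Residual matrix over the kept subjects; attribute `kept` holds
#'   their row indices.
#' @export
residualize_site <- function(loadings, site) {
  loadings <- as.matrix(loadings)
  site <- as.character(site)
  stopifnot(length(site) == nrow(loadings))
  tab <- table(site)
  singles <- names(tab)[tab < 2L]
  keep <- !(site %in% singles)
  if (length(singles)) {
    warning(sprintf("dropping %d singleton site(s): %s", length(singles),
                    paste(singles, collapse = ", ")))
  }
  site_f <- factor(site[keep])
  if (nlevels(site_f) < 2L) {
    lf_stop("need at least 2 sites with >= 2 subjects each",
            "longfuse_config_error")
  }
  Xm <- stats::model.matrix(~site_f)
  res <- lm.fit(Xm, loadings[keep, , drop = FALSE])$residuals
  res <- as.matrix(res)
  dimnames(res) <- dimnames(loadings[keep, , drop = FALSE])
  attr(res, "kept") <- which(keep)
  res
}

#' Fisher z test for the difference of two independent correlations
#'
#' @param r1,r2 Correlations.
#' @param n1,n2 Group sizes (must exceed 3).
#' @return List with `z`, `p` (two-sided) and `ci` function-free 95%
#'   confidence bounds for `r1 - r2` on the correlation scale obtained by
#'   back-transforming the z-scale interval of `atanh(r1) - atanh(r2)`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  dz <- atanh(clamp(r1)) - atanh(clamp(r2))
  z <- dz / se
  lo <- dz - qnorm(0.975) * se
  hi <- dz + qnorm(0.975) * se
  list(z = z, p = 2 * pnorm(-abs(z)),
       dz = dz, dz_lo = lo, dz_hi = hi)
}
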