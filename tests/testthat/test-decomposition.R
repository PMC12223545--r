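test_that("whitening yields identity covariance and consistent back-projection", {
  set.seed(1)
  X <- matrix(rnorm(30 * 400), 30) * rep(seq(1, 4, length.out = 30), 400)
  pm <- pca_model(X, 6)
  Y <- pca_project(pm, X)
  expect_lt(max(abs(tcrossprod(Y) / (ncol(X) - 1) - diag(6))), 1e-8)
  # back-projection recovers the projection of X onto the retained subspace
  Xb <- pca_backproject(pm, Y)
  Yb <- pca_project(pm, Xb)
  expect_lt(max(abs(Yb - Y)), 1e-8)
  expect_true(all(diff(pm$eigenvalues) <= 1e-10))
})

test_that("elbow selection maximizes chord distance and honors overrides", {
  ev <- c(10, 5, 2.5, 1.2, 1.1, 1.05, 1.0)
  # brute-force oracle: evaluate the point-to-chord distance at every index
  m <- length(ev)
  x <- (seq_len(m) - 1) / (m - 1)
  y <- (ev - min(ev)) / (max(ev) - min(ev))
  dy <- y[m] - y[1]
  oracle <- which.max(abs(dy * x - (y - y[1])) / sqrt(1 + dy^2))
  expect_equal(select_components_elbow(ev), oracle)
  expect_equal(select_components_elbow(ev, override = 5), 5L)
  # random descending spectra agree with the oracle too
  set.seed(2)
  for (i in 1:20) {
    ev_i <- sort(rexp(15) + 0.05, decreasing = TRUE)
    y_i <- (ev_i - min(ev_i)) / (max(ev_i) - min(ev_i))
    x_i <- (0:14) / 14
    dy_i <- y_i[15] - y_i[1]
    oracle_i <- which.max(abs(dy_i * x_i - (y_i - y_i[1])) / sqrt(1 + dy_i^2))
    expect_equal(select_components_elbow(ev_i), oracle_i)
  }
  expect_warning(k1 <- select_components_elbow(seq(10, 1, length.out = 8)),
                 "linear")
  expect_equal(k1, 1L)
  expect_error(select_components_elbow(c(1, 2, 3)), "non-increasing")
})

test_that("infomax separates sparse supergaussian mixtures almost exactly", {
  S <- lf_sparse_sources(3, 500, seed = 3)
  set.seed(4)
  A_true <- matrix(rnorm(6 * 3), 6, 3)
  X <- A_true %*% S
  fit <- infomax_ica(X, 3, seed = 1)
  expect_true(fit$converged)
  # Amari index of the unmixing against the whitened true mixing
  pm <- pca_model(X, 3)
  mt <- match_sources(fit$sources$fnc, S)
  W_eff <- cor(t(fit$sources$fnc), t(pca_project(pm, X)))
  expect_lt(amari_index(W_eff, pm$whiten %*% A_true), 0.01)
  expect_true(all(abs(mt$r) > 0.99))
})

test_that("one-component ICA returns the first principal axis up to sign", {
  set.seed(5)
  X <- matrix(rnorm(40 * 300), 40)
  fit <- infomax_ica(X, 1, seed = 2)
  pm <- pca_model(X, 1)
  pc1 <- drop(pca_project(pm, X))
  r <- cor(drop(fit$sources$fnc), pc1)
  expect_gt(abs(r), 1 - 1e-6)
})

test_that("ICA obeys feature-permutation and scaling equivariance", {
  S <- lf_sparse_sources(3, 400, seed = 6)
  set.seed(7)
  X <- matrix(rnorm(8 * 3), 8) %*% S
  fit <- infomax_ica(X, 3, seed = 3)
  perm <- sample(ncol(X))
  fit_p <- infomax_ica(X[, perm], 3, seed = 3)
  expect_equal(fit_p$sources$fnc, fit$sources$fnc[, perm], tolerance = 1e-6)
  expect_equal(fit_p$loadings$fnc, fit$loadings$fnc, tolerance = 1e-6)
  fit_s <- infomax_ica(3 * X, 3, seed = 3)
  expect_equal(fit_s$loadings$fnc, 3 * fit$loadings$fnc, tolerance = 1e-6)
  expect_equal(fit_s$sources$fnc, fit$sources$fnc, tolerance = 1e-6)
})

test_that("two-set mCCA equals classical CCA and flags rank deficiency", {
  set.seed(8)
  for (i in 1:5) {
    Y1 <- matrix(rnorm(50 * 10), 50)
    Y2 <- matrix(rnorm(50 * 10), 50)
    m <- mcca(list(Y1, Y2), k = 3)
    expect_lt(max(abs(m$canonical_correlations - lf_cca_oracle(Y1, Y2, 3))),
              1e-8)
    expect_true(all(diff(m$canonical_correlations) <= 1e-10))
  }
  Y1 <- matrix(rnorm(50 * 10), 50)
  m_id <- mcca(list(Y1, Y1), k = 3)
  expect_equal(m_id$canonical_correlations, rep(1, 3), tolerance = 1e-8)
  Ylow <- Y1[, 1:2] %*% matrix(rnorm(2 * 10), 2)
  expect_error(mcca(list(Y1, Ylow), k = 3), "rank")
})

test_that("independent sets produce only null-level canonical correlations", {
  set.seed(9)
  n <- 2000
  Y1 <- matrix(rnorm(n * 8), n)
  Y2 <- matrix(rnorm(n * 8), n)
  m <- mcca(list(Y1, Y2), k = 3)
  # permutation null for the largest canonical correlation
  null_cc <- replicate(100, lf_cca_oracle(Y1[sample(n), ], Y2, 1))
  expect_lt(max(m$canonical_correlations), quantile(null_cc, 0.95) * 1.05)
})

test_that("mcca_jica reconstructs noiseless data and recovers planted sources", {
  co0 <- simulate_cohort(n_subjects = 80, noise_sd = 0, seed = 10)
  fit0 <- mcca_jica(co0$delta_fnc, co0$delta_gmv, k = 5, seed = 1)
  expect_lt(max(fit0$info$recon_error), 1e-6)
  co <- lf_cached_cohort(seed = 1)
  fit <- mcca_jica(co$delta_fnc, co$delta_gmv, k = 5, seed = 1)
  mf <- match_sources(fit$sources$fnc, co$truth$S_F_true)
  mg <- match_sources(fit$sources$gmv, co$truth$S_G_true)
  expect_gt(median(abs(mf$r)), 0.9)
  expect_gt(median(abs(mg$r)), 0.9)
  expect_error(mcca_jica(co$delta_fnc[1:100, ], co$delta_gmv, k = 5),
               "subject")
})

test_that("a shared mean change surfaces as a negative loading T (age increase)", {
  truth <- simulate_ground_truth(n_subjects = 400, seed = 12)
  # subjects share an expression increase over time on component 2; under
  # the baseline-minus-followup convention that is a negative loading mean
  truth$A_F_true[, 2] <- truth$A_F_true[, 2] - 0.6
  co <- assemble_cohort(truth)
  fit <- fuse_sym(co$delta_fnc, co$delta_gmv, k = 5, seed = 12)
  mt <- match_sources(fit$fusion$sources$fnc, truth$S_F_true)
  j <- mt$est[mt$truth == 2]
  sgn <- sign(mt$r[mt$truth == 2])
  row <- fit$loading_stats[fit$loading_stats$modality == "fnc" &
                             fit$loading_stats$component == j, ]
  expect_lt(sgn * row$statistic, -5)
  if (sgn > 0) expect_equal(row$direction, "increase-with-age")
  # other functional components stay unlabelled
  others <- fit$loading_stats[fit$loading_stats$modality == "fnc" &
                                fit$loading_stats$component != j, ]
  expect_true(all(abs(others$statistic) < 3))
})

test_that("sign/order canonicalization is idempotent and product-preserving", {
  co <- lf_cached_cohort(seed = 1)
  fit <- mcca_jica(co$delta_fnc, co$delta_gmv, k = 5, seed = 1)
  prod_before <- fit$loadings$fnc %*% fit$sources$fnc
  fit2 <- fix_signs_and_order(fit)
  expect_equal(fit2$sources$fnc, fit$sources$fnc)
  expect_equal(fit2$loadings$gmv, fit$loadings$gmv)
  expect_lt(max(abs(fit2$loadings$fnc %*% fit2$sources$fnc - prod_before)),
            1e-12)
  # a negated source row is restored to the same canonical form
  fit_neg <- fit
  fit_neg$sources$fnc[2, ] <- -fit_neg$sources$fnc[2, ]
  fit_neg$sources$gmv[2, ] <- -fit_neg$sources$gmv[2, ]
  fit_neg$loadings$fnc[, 2] <- -fit_neg$loadings$fnc[, 2]
  fit_neg$loadings$gmv[, 2] <- -fit_neg$loadings$gmv[, 2]
  fit3 <- fix_signs_and_order(fit_neg)
  expect_equal(fit3$sources$fnc, fit$sources$fnc)
  expect_equal(fit3$loadings$fnc, fit$loadings$fnc)
  # unit-norm source rows after canonicalization
  expect_equal(unname(sqrt(rowSums(fit2$sources$gmv^2))), rep(1, 5))
})
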