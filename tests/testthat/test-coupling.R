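test_that("voxel-wise coupling equals a brute-force correlation loop", {
  set.seed(1)
  n <- 40; V <- 25
  x <- rnorm(n)
  G <- matrix(rnorm(n * V), n, V)
  G[, 7] <- x                                  # perfectly coupled voxel
  cm <- voxelwise_coupling(x, G, 0.05)
  expect_equal(cm$r[7], 1)
  brute_r <- vapply(seq_len(V), function(v) cor(x, G[, v]), numeric(1))
  brute_p <- vapply(seq_len(V), function(v) cor.test(x, G[, v])$p.value,
                    numeric(1))
  expect_lt(max(abs(cm$r - brute_r)), 1e-12)
  expect_lt(max(abs(cm$p[-7] - brute_p[-7])), 1e-12)
  expect_true(all(cm$q >= cm$p - 1e-15))
  # constant voxels are excluded from the FDR family
  G[, 3] <- 2
  expect_message(cm2 <- voxelwise_coupling(x, G, 0.05), "constant")
  expect_true(is.na(cm2$r[3]) && is.na(cm2$q[3]) && !cm2$sig_mask[3])
})

test_that("planted blob coupling is detected with Dice above 0.5", {
  co <- lf_cached_cohort(seed = 2)
  for (j in c(2, 3)) {
    region <- co$truth$S_G_true[j, ] > 0.25
    cm <- voxelwise_coupling(co$truth$A_F_true[, j], co$delta_gmv, 0.05)
    dice <- 2 * sum(cm$sig_mask & region) /
      (sum(cm$sig_mask) + sum(region))
    expect_gt(dice, 0.5)
  }
})

test_that("sex contrast maps are antisymmetric and detect female-only coupling", {
  set.seed(3)
  n <- 400; V <- 300
  sex <- rep(c("F", "M"), each = n / 2)
  x <- rnorm(n)
  G <- matrix(rnorm(n * V), n, V)
  region <- 1:30
  G[sex == "F", region] <- G[sex == "F", region] + 0.8 * x[sex == "F"]
  gc <- gender_contrast_asym(x, G, sex, q_threshold = 0.001)
  expect_gt(mean(gc$difference[region]), 0.2)
  expect_gt(sum(gc$sig_mask[region]), 0)
  # swapping the labels negates the difference map exactly
  sex_sw <- ifelse(sex == "F", "M", "F")
  gc_sw <- gender_contrast_asym(x, G, sex_sw, q_threshold = 0.001)
  expect_equal(gc_sw$difference, -gc$difference)
  # identical coupling in both sexes: null difference, no flood of hits
  G0 <- matrix(rnorm(n * V), n, V) + 0.5 * x
  gc0 <- gender_contrast_asym(x, G0, sex, q_threshold = 0.001)
  expect_lt(max(abs(gc0$difference)), 0.35)
  expect_lt(sum(gc0$sig_mask), 3)
  expect_error(gender_contrast_asym(x[1:15], G[1:15, ], rep(c("F", "M"),
                                                            c(12, 3))),
               "at least 10")
})

test_that("loading-pair sex contrast flags the planted component only", {
  n <- 4000
  sex <- rep(c("F", "M"), each = n / 2)
  ld <- linked_loadings(n, 5, rho = 0.3, rho_sex = c(0, 0.2, 0, 0, 0),
                        sex = sex, seed = 4)
  res <- fusion_result(loadings = list(fnc = ld$A_F, gmv = ld$A_G),
                       sources = list(fnc = diag(5), gmv = diag(5)),
                       k = 5, method = "planted")
  gc <- gender_contrast_sym(res, sex)
  expect_true(gc$sig_mask[2, 2])
  expect_equal(sum(gc$sig_mask), 1L)
  expect_true(gc$dz_lo[2, 2] < atanh(0.5) - atanh(0.3) &&
                atanh(0.5) - atanh(0.3) < gc$dz_hi[2, 2])
  # exchanging the modalities transposes the difference grid
  res_sw <- fusion_result(loadings = list(fnc = ld$A_G, gmv = ld$A_F),
                          sources = list(fnc = diag(5), gmv = diag(5)),
                          k = 5, method = "planted")
  gc_sw <- gender_contrast_sym(res_sw, sex)
  expect_equal(gc_sw$difference, t(gc$difference))
  # null: no significant pair
  ld0 <- linked_loadings(n, 5, rho = 0.3, rho_sex = 0, sex = sex, seed = 5)
  res0 <- fusion_result(loadings = list(fnc = ld0$A_F, gmv = ld0$A_G),
                        sources = list(fnc = diag(5), gmv = diag(5)),
                        k = 5, method = "planted")
  expect_equal(sum(gender_contrast_sym(res0, sex)$sig_mask), 0L)
})

test_that("quartile membership follows the within-or-below convention", {
  set.seed(6)
  n <- 40
  scores <- rep(1:8, each = 5)
  x <- rnorm(n)
  G <- matrix(rnorm(n * 20), n, 20)
  qc <- quartile_contrast(x, G, scores)
  # quartiles of 1..8 replicated: Q1 = 2.75, Q3 = 6.25
  expect_equal(unname(qc$n[["lower"]]), sum(scores <= 2.75))
  expect_equal(unname(qc$n[["upper"]]), sum(scores >= 6.25))
  expect_equal(qc$lower_map$n_subjects_used, 10L)
  expect_error(quartile_contrast(x, G, rep(1, n)), "degenerate")
  expect_error(quartile_contrast(x[1:20], G[1:20, ], scores[1:20]), "40")
})

test_that("quartile contrast is negative where only low scorers are coupled", {
  set.seed(7)
  n <- 200; V <- 400
  x <- rnorm(n)
  scores <- rnorm(n)
  G <- matrix(rnorm(n * V), n, V)
  region <- 1:40
  low <- scores <= quantile(scores, 0.25)
  G[low, region] <- G[low, region] + x[low]
  qc <- quartile_contrast(x, G, scores)
  expect_lt(mean(qc$difference[region]), -0.3)
  # homogeneous coupling: difference near zero, no significant voxels
  G2 <- matrix(rnorm(n * V), n, V) + 0.6 * x
  qc2 <- quartile_contrast(x, G2, scores)
  expect_lt(mean(abs(qc2$difference)), 0.2)
  expect_equal(sum(qc2$sig_mask), 0L)
})
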