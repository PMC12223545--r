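lf_make_tt <- function(n_t = 380, tr = 0.8) (0:(n_t - 1)) * tr

test_that("polynomial trends and motion combinations are removed exactly", {
  tt <- lf_make_tt()
  cubic <- sapply(1:4, function(j) 0.5 * tt^3 - 2 * tt^2 + j * tt + j)
  out <- postprocess_timecourses(timecourse_set(cubic, 0.8))
  expect_lt(max(abs(out$tc)), 1e-6)
  # smooth motion (no despiking triggered), arbitrary mixing into the TCs
  mot <- sapply(1:6, function(j) sin(2 * pi * tt / (20 + j)) +
                  0.3 * cos(2 * pi * tt / (7 + j)))
  set.seed(1)
  tcm <- mot %*% matrix(rnorm(6 * 4), 6)
  out2 <- postprocess_timecourses(timecourse_set(tcm, 0.8, motion = mot))
  expect_lt(max(abs(out2$tc)), 1e-8)
})

test_that("the bandpass attenuates 0.2 Hz by at least 20 dB at TR 0.8 s", {
  tt <- lf_make_tt()
  x_stop <- sin(2 * pi * 0.2 * tt)
  x_pass <- sin(2 * pi * 0.05 * tt)
  out <- postprocess_timecourses(timecourse_set(cbind(x_stop, x_pass), 0.8),
                                 outlier_z = Inf)
  mid <- 100:280   # steady-state region away from filter edges
  att <- 20 * log10(max(abs(out$tc[mid, 1])) / max(abs(x_stop[mid])))
  keep <- 20 * log10(max(abs(out$tc[mid, 2])) / max(abs(x_pass[mid])))
  expect_lt(att, -20)
  expect_gt(keep, -3)
  expect_error(
    postprocess_timecourses(timecourse_set(matrix(rnorm(22 * 3), 22), 0.8)),
    "at least [0-9]+ time points")
})

test_that("despiking replaces isolated large excursions", {
  tt <- lf_make_tt()
  set.seed(2)
  x <- sin(2 * pi * 0.05 * tt) + 0.05 * rnorm(length(tt))
  x_sp <- x
  x_sp[c(60, 200)] <- x_sp[c(60, 200)] + 25
  ts_clean <- timecourse_set(cbind(x, x), 0.8)
  ts_spike <- timecourse_set(cbind(x_sp, x), 0.8)
  out_c <- postprocess_timecourses(ts_clean)
  out_s <- postprocess_timecourses(ts_spike)
  # despiked output close to the clean pipeline, nowhere near spike size
  expect_lt(max(abs(out_s$tc[, 1] - out_c$tc[, 1])), 0.5)
})

test_that("FNC estimation is a Pearson correlation with unit diagonal", {
  set.seed(3)
  tc <- matrix(rnorm(600 * 4), 600)
  tc[, 2] <- tc[, 1]                        # duplicated network
  fnc <- compute_fnc(tc)
  expect_equal(fnc[1, 2], 1)
  expect_equal(diag(fnc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(fnc)[3, 4], cor(tc[, 3], tc[, 4]))
  # orthogonal sine and cosine over whole periods
  tt <- seq(0, 10 - 1e-9, length.out = 1000)
  fnc2 <- compute_fnc(cbind(sin(2 * pi * tt), cos(2 * pi * tt)))
  expect_lt(abs(fnc2[1, 2]), 1e-2)
  # TCs simulated from a target covariance recover it within sampling error
  R_target <- matrix(c(1, .6, .2, .6, 1, -.3, .2, -.3, 1), 3)
  set.seed(4)
  Z <- matrix(rnorm(20000 * 3), ncol = 3) %*% chol(R_target)
  fnc3 <- compute_fnc(Z)
  expect_lt(max(abs(unclass(fnc3) - R_target)), 3 / sqrt(20000) * 3)
  expect_warning(compute_fnc(cbind(tc[, 1], rep(1, 600))), "zero-variance")
})

test_that("FNC vectorization is row-major upper triangle and round-trips", {
  m <- matrix(c(1, .5, .2, .5, 1, -.3, .2, -.3, 1), 3)
  expect_equal(fnc_vectorize(m), c(.5, .2, -.3))
  expect_equal(length(fnc_vectorize(diag(53))), 1378L)
  set.seed(5)
  A <- matrix(rnorm(64), 8); A <- A + t(A); diag(A) <- 1
  expect_equal(fnc_devectorize(fnc_vectorize(A), 8), A)
  expect_error(fnc_devectorize(1:5, 4), "n\\(n-1\\)/2")
  expect_error(fnc_vectorize(matrix(1:9, 3)), "symmetric")
})

test_that("QC thresholds follow the 0.75/0.55/0.8 rule and ignore scan order", {
  expect_false(qc_report(0.74, 0.6, 0.85)$passed)
  expect_true(qc_report(0.8, 0.6, 0.85)$passed)
  expect_false(qc_report(0.8, 0.54, 0.85)$passed)
  expect_false(qc_report(0.8, 0.6, 0.79)$passed)
  # identical masks: r = 1 everywhere, passed
  set.seed(6)
  base <- array(runif(10 * 10 * 24) > 0.35, c(10, 10, 24))
  rep_masks <- list(base, base, base)
  rp <- qc_masks(rep_masks)
  expect_equal(rp$r_top10, rep(1, 3))
  expect_true(all(rp$passed))
  # pass set invariant to scan ordering
  masks <- lapply(1:5, function(i) {
    m <- base
    flip <- sample(length(m), 40 * i)
    m[flip] <- !m[flip]
    m
  })
  r1 <- qc_masks(masks)
  perm <- c(3, 5, 1, 4, 2)
  r2 <- qc_masks(masks[perm])
  expect_equal(r2$passed, r1$passed[perm])
  expect_error(qc_masks(list(array(TRUE, c(5, 5, 12)))), "20 axial slices")
})

test_that("delta matrices subtract follow-up from baseline and are antisymmetric", {
  set.seed(7)
  b <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("s", 1:4), NULL))
  f <- matrix(rnorm(20), 4, 5, dimnames = dimnames(b))
  d <- build_delta(b, f, "fnc_cells")
  expect_equal(d$data, b - f)
  d_swap <- build_delta(f, b, "fnc_cells")
  expect_equal(d_swap$data, -d$data)
  expect_equal(build_delta(b, b, "fnc_cells")$data, b * 0)
  # a single changed cell
  f2 <- b; f2[2, 3] <- b[2, 3] - 0.2
  expect_equal(unname(build_delta(b, f2, "fnc_cells")$data[2, 3]), 0.2)
  # subjects missing a timepoint are excluded
  expect_message(d3 <- build_delta(b, f[1:3, , drop = FALSE], "fnc_cells"),
                 "excluded 1")
  expect_equal(d3$subject_ids, paste0("s", 1:3))
  rownames(f) <- paste0("x", 1:4)
  expect_error(build_delta(b, f, "fnc_cells"), "both timepoints")
})
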