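#' Default network-domain partition
#'
#' A named vector of domain sizes for the 53-network parcellation used
#' throughout the package: subcortical, auditory, sensorimotor, visual,
#' cognitive control, default mode and cerebellar domains. The sizes are a
#' configurable default, not a fixed fact of the parcellation; any named
#' partition summing to the network count may be supplied instead.
#'
#' @return Named integer vector of domain sizes summing to 53.
#' @export
default_domains <- function() {
  c(subcortical = 5L, auditory = 2L, sensorimotor = 9L, visual = 9L,
    cognitive_control = 17L, default_mode = 7L, cerebellar = 4L)
}

#' Generate block-structured FNC change-pattern sources
#'
#' Each source is the upper-triangle vectorization (row-major, diagonal
#' excluded) of a symmetric zero-diagonal network-by-network matrix whose
#' nonzero entries are concentrated in a small number of domain-by-domain
#' blocks. Within a block, entries share a random sign and have magnitudes
#' drawn from Uniform(0.5, 1), giving sparse, supergaussian-mixable patterns
#' that mimic the modular connectivity change patterns seen in real FNC
#' decompositions. Blocks are sampled without replacement across components,
#' so distinct sources have disjoint support and are mutually near-orthogonal.
#'
#' @param n_networks Number of networks (default 53).
#' @param domain_sizes Named integer partition of the networks into domains;
#'   must sum to `n_networks`.
#' @param k Number of sources to generate.
#' @param blocks_per_source Optional integer (or length-`k` vector) fixing the
#'   number of domain blocks per source; default samples 1-3 per source.
#' @param seed Integer seed; fully determines the output.
#' @return A `k x n_networks*(n_networks-1)/2` matrix. Attribute `blocks`
#'   lists the domain-pair blocks used by each source.
#' @export
fcp_sources <- function(n_networks = 53L, domain_sizes = default_domains(),
                        k = 5L, blocks_per_source = NULL, seed = 1L) {
  if (sum(domain_sizes) != n_networks) {
    lf_stop(sprintf(
      "domain_sizes sums to %d but n_networks is %d",
      sum(domain_sizes), n_networks), "longfuse_config_error")
  }
  if (k < 1) lf_stop("k must be >= 1", "longfuse_config_error")
  nd <- length(domain_sizes)
  # all unordered domain pairs, including within-domain blocks
  pairs <- which(upper.tri(diag(nd), diag = TRUE), arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  if (k > n_pairs) {
    lf_stop(sprintf(
      "k = %d exceeds the %d available domain blocks; enlarge the partition",
      k, n_pairs), "longfuse_config_error")
  }
  set.seed(lf_seed(seed))
  max_per <- max(1L, min(3L, n_pairs %/% k))
  nb <- if (is.null(blocks_per_source)) {
    sample.int(max_per, k, replace = TRUE)
  } else rep_len(as.integer(blocks_per_source), k)
  if (sum(nb) > n_pairs) nb <- rep_len(1L, k)
  block_order <- sample.int(n_pairs)
  ends <- cumsum(c(domain_sizes))
  starts <- ends - domain_sizes + 1L
  n_cells <- n_networks * (n_networks - 1L) / 2L
  S <- matrix(0, k, n_cells)
  blocks <- vector("list", k)
  ptr <- 1L
  for (j in seq_len(k)) {
    ids <- block_order[ptr:(ptr + nb[j] - 1L)]
    ptr <- ptr + nb[j]
    M <- matrix(0, n_networks, n_networks)
    for (b in ids) {
      d1 <- pairs[b, 1L]; d2 <- pairs[b, 2L]
      i1 <- starts[d1]:ends[d1]; i2 <- starts[d2]:ends[d2]
      sgn <- sample(c(-1, 1), 1L)
      vals <- matrix(sgn * runif(length(i1) * length(i2), 0.5, 1),
                     length(i1), length(i2))
      M[i1, i2] <- vals
      M[i2, i1] <- t(vals)
    }
    # symmetrize within-domain blocks and zero the diagonal
    M <- (M + t(M)) / 2
    diag(M) <- 0
    S[j, ] <- fnc_vectorize(M)
    blocks[[j]] <- pairs[ids, , drop = FALSE]
  }
  attr(S, "blocks") <- blocks
  attr(S, "domain_sizes") <- domain_sizes
  S
}

#' Generate Gaussian-blob structural change-pattern sources
#'
#' Each source is a sum of 1-3 isotropic Gaussian blobs with centers inside
#' the mask, peak-normalized to 1 and restricted to in-mask voxels. These
#' emulate the compact gray-matter change maps produced by fusion analyses.
#'
#' @param grid_shape Integer length-3 volume dimensions.
#' @param mask Logical 3D array of the same shape; default is the full grid.
#' @param k Number of sources.
#' @param n_blobs Optional integer (or length-`k` vector) fixing the blob
#'   count per source; default samples 1-3.
#' @param seed Integer seed.
#' @return A `k x sum(mask)` matrix with attributes `centers` (list of
#'   blob-center matrices), `sigmas`, `mask` and `grid_shape`.
#' @export
scp_sources <- function(grid_shape, mask = NULL, k = 5L, n_blobs = NULL,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  if (!identical(dim(mask), grid_shape)) {
    lf_stop("mask dimensions do not match grid_shape", "longfuse_config_error")
  }
  n_vox <- sum(mask)
  if (n_vox == 0L) lf_stop("mask is empty", "longfuse_config_error")
  if (k < 1) lf_stop("k must be >= 1", "longfuse_config_error")
  set.seed(lf_seed(seed))
  nb <- if (is.null(n_blobs)) sample.int(3L, k, replace = TRUE) else
    rep_len(as.integer(n_blobs), k)
  coords <- which(mask, arr.ind = TRUE)   # n_vox x 3, C-order-free linear index
  S <- matrix(0, k, n_vox)
  centers <- vector("list", k)
  sigmas <- vector("list", k)
  for (j in seq_len(k)) {
    ctr <- coords[sample.int(n_vox, nb[j]), , drop = FALSE]
    sg <- runif(nb[j], 1.2, 2.5)
    v <- numeric(n_vox)
    for (b in seq_len(nb[j])) {
      d2 <- (coords[, 1] - ctr[b, 1])^2 + (coords[, 2] - ctr[b, 2])^2 +
        (coords[, 3] - ctr[b, 3])^2
      v <- v + exp(-d2 / (2 * sg[b]^2))
    }
    S[j, ] <- v / max(v)
    centers[[j]] <- ctr
    sigmas[[j]] <- sg
  }
  attr(S, "centers") <- centers
  attr(S, "sigmas") <- sigmas
  attr(S, "mask") <- mask
  attr(S, "grid_shape") <- grid_shape
  S
}

#' Sample cross-modally linked subject loadings
#'
#' For each component j the functional and structural loading columns are
#' drawn from a bivariate normal with unit variances and correlation
#' `rho[j] + rho_sex[j]` for female subjects and `rho[j]` for male subjects.
#' Components are mutually independent. This plants both a per-component
#' structure-function coupling and a sex difference in that coupling.
#'
#' @param n_subjects Number of subjects.
#' @param k Number of components.
#' @param rho Length-`k` (or scalar) baseline coupling in \[-1, 1\].
#' @param rho_sex Length-`k` (or scalar) female-minus-male coupling offset.
#' @param sex Character/factor vector of length `n_subjects` with levels
#'   "F" and "M".
#' @param seed Integer seed.
#' @return List with `A_F` and `A_G`, both `n_subjects x k`.
#' @export
linked_loadings <- function(n_subjects, k, rho = 0, rho_sex = 0, sex, seed = 1L) {
  rho <- rep_len(rho, k)
  rho_sex <- rep_len(rho_sex, k)
  sex <- as.character(sex)
  if (length(sex) != n_subjects) {
    lf_stop("sex must have one entry per subject", "longfuse_config_error")
  }
  if (!all(sex %in% c("F", "M"))) {
    lf_stop("sex labels must be 'F' or 'M'", "longfuse_config_error")
  }
  if (any(abs(rho) > 1) || any(abs(rho + rho_sex) > 1)) {
    lf_stop("implied correlations rho and rho + rho_sex must lie in [-1, 1]",
            "longfuse_config_error")
  }
  set.seed(lf_seed(seed))
  A_F <- matrix(rnorm(n_subjects * k), n_subjects, k)
  E <- matrix(rnorm(n_subjects * k), n_subjects, k)
  is_f <- sex == "F"
  A_G <- matrix(0, n_subjects, k)
  for (j in seq_len(k)) {
    r <- ifelse(is_f, rho[j] + rho_sex[j], rho[j])
    A_G[, j] <- r * A_F[, j] + sqrt(1 - r^2) * E[, j]
  }
  list(A_F = A_F, A_G = A_G)
}

#' Simulate the ground truth of a linked multimodal cohort
#'
#' Draws demographics (sex, ages in months at both timepoints, site), the
#' block-structured FNC sources, blob-structured GMV sources and linked
#' loadings, and packages them with the generative parameters. The defaults
#' describe the package's reference simulation: 500 subjects, 53 networks in
#' 7 domains (1378 connectivity cells), a 12 x 14 x 12 voxel grid
#' (2016 voxels), 5 components, cross-modal coupling 0.5 and residual noise
#' standard deviation 0.2.
#'
#' @param n_subjects,n_networks,domain_sizes,grid_shape,mask,k See details.
#' @param rho,rho_sex Planted coupling and its female-minus-male offset
#'   (scalar or length-`k`).
#' @param beta_psych,beta_cog Length-`k` linear effects of the functional
#'   loadings on the change in composite psychopathology / cognition scores.
#'   Defaults (for `k >= 5`) tie the psychopathology change to components 4
#'   and 5 and the cognition change to components 2 and 5.
#' @param noise_sd Residual standard deviation of both data matrices.
#' @param score_noise_sd Residual standard deviation of the score model.
#' @param n_sites Number of acquisition sites (default 21).
#' @param seed Integer seed; fully determines the cohort.
#' @return An object of class `ground_truth`.
#' @export
simulate_ground_truth <- function(n_subjects = 500L, n_networks = 53L,
                                  domain_sizes = default_domains(),
                                  grid_shape = c(12L, 14L, 12L), mask = NULL,
                                  k = 5L, rho = 0.5, rho_sex = 0,
                                  beta_psych = NULL, beta_cog = NULL,
                                  noise_sd = 0.2, score_noise_sd = 1,
                                  n_sites = 21L, seed = 1L) {
  rho <- rep_len(rho, k)
  rho_sex <- rep_len(rho_sex, k)
  if (is.null(beta_psych)) {
    beta_psych <- numeric(k)
    if (k >= 5) beta_psych[c(4L, 5L)] <- -0.3
  }
  if (is.null(beta_cog)) {
    beta_cog <- numeric(k)
    if (k >= 5) beta_cog[c(2L, 5L)] <- c(0.3, -0.3)
  }
  set.seed(lf_seed(seed))
  sex <- sample(c("F", "M"), n_subjects, replace = TRUE, prob = c(0.478, 0.522))
  age0 <- round(rnorm(n_subjects, 119, 8))
  age2 <- age0 + 24L
  site <- sample(sprintf("site%02d", seq_len(n_sites)), n_subjects,
                 replace = TRUE)
  demographics <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n_subjects)),
    sex = sex, age_months_t0 = age0, age_months_t2 = age2, site = site,
    stringsAsFactors = FALSE)

  S_F <- fcp_sources(n_networks, domain_sizes, k, seed = lf_seed(seed, 1L))
  S_G <- scp_sources(grid_shape, mask, k, seed = lf_seed(seed, 2L))
  ld <- linked_loadings(n_subjects, k, rho, rho_sex, sex,
                        seed = lf_seed(seed, 3L))
  structure(list(
    S_F_true = S_F, S_G_true = S_G,
    A_F_true = ld$A_F, A_G_true = ld$A_G,
    rho = rho, rho_sex = rho_sex,
    beta_psych = beta_psych, beta_cog = beta_cog,
    noise_sd = noise_sd, score_noise_sd = score_noise_sd,
    demographics = demographics, mask = attr(S_G, "mask"),
    grid_shape = attr(S_G, "grid_shape"), k = k, seed = as.integer(seed)
  ), class = "ground_truth")
}

#' Assemble a synthetic cohort from its ground truth
#'
#' Forms the change matrices as low-rank mixtures plus Gaussian noise,
#' `delta_fnc = A_F S_F + E_F` and `delta_gmv = A_G S_G + E_G`, and the
#' score changes as linear combinations of the functional loadings plus
#' noise. Identical ground truths (hence identical seeds) reproduce
#' bit-identical cohorts.
#'
#' @param truth A `ground_truth` object.
#' @return An object of class `synthetic_cohort` with elements `delta_fnc`,
#'   `delta_gmv`, `mask`, `demographics`, `delta_psych`, `delta_cog`, `truth`.
#' @export
assemble_cohort <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(truth$A_F_true)
  set.seed(lf_seed(truth$seed, 7L))
  delta_fnc <- truth$A_F_true %*% truth$S_F_true
  delta_gmv <- truth$A_G_true %*% truth$S_G_true
  if (truth$noise_sd > 0) {
    delta_fnc <- delta_fnc + truth$noise_sd * matrix(rnorm(length(delta_fnc)),
                                                     nrow = n)
    delta_gmv <- delta_gmv + truth$noise_sd * matrix(rnorm(length(delta_gmv)),
                                                     nrow = n)
  }
  delta_psych <- drop(truth$A_F_true %*% truth$beta_psych) +
    truth$score_noise_sd * rnorm(n)
  delta_cog <- drop(truth$A_F_true %*% truth$beta_cog) +
    truth$score_noise_sd * rnorm(n)
  rownames(delta_fnc) <- rownames(delta_gmv) <- truth$demographics$subject_id
  structure(list(
    delta_fnc = delta_fnc, delta_gmv = delta_gmv,
    mask = truth$mask, demographics = truth$demographics,
    delta_psych = delta_psych, delta_cog = delta_cog, truth = truth
  ), class = "synthetic_cohort")
}

#' Simulate a linked multimodal cohort in one call
#'
#' Convenience wrapper: `assemble_cohort(simulate_ground_truth(...))`.
#'
#' @inheritParams simulate_ground_truth
#' @param ... Passed to [simulate_ground_truth()].
#' @return A `synthetic_cohort`.
#' @export
simulate_cohort <- function(..., seed = 1L) {
  assemble_cohort(simulate_ground_truth(..., seed = seed))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d subjects, %d FNC cells, %d GMV voxels, k = %d\n",
    nrow(x$delta_fnc), ncol(x$delta_fnc), ncol(x$delta_gmv), x$truth$k))
  cat(sprintf("  rho = %s; rho_sex = %s; noise_sd = %.3g; seed = %d\n",
              paste(format(x$truth$rho), collapse = ", "),
              paste(format(x$truth$rho_sex), collapse = ", "),
              x$truth$noise_sd, x$truth$seed))
  invisible(x)
}
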