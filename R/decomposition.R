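#' Fit a PCA / whitening model over matrix rows
#'
#' Treats the rows of `X` (e.g., subjects, or concatenated feature maps) as
#' variables and the columns as observations. Retains the top `k`
#' eigenvectors of the row covariance; the projection whitens (identity
#' covariance), and back-projection composed with projection is the identity
#' on the retained subspace.
#'
#' @param X Numeric matrix.
#' @param k Number of retained components.
#' @param center Subtract row means first (default TRUE).
#' @return An object of class `pca_model` with elements `mean`,
#'   `eigenvalues` (all, descending), `whiten` (`k x nrow(X)`), `dewhiten`
#'   (`nrow(X) x k`).
#' @export
pca_model <- function(X, k, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p)) {
    lf_stop(sprintf("k = %d exceeds the matrix rank bound %d", k, min(n, p)),
            "longfuse_config_error")
  }
  mu <- if (center) rowMeans(X) else rep(0, n)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (p - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (ev[k] <= 1e-12 * max(ev)) {
    lf_stop(sprintf("rank deficiency: eigenvalue %d is numerically zero; choose a smaller k", k),
            "longfuse_config_error")
  }
  V <- e$vectors[, seq_len(k), drop = FALSE]
  d <- sqrt(ev[seq_len(k)])
  structure(list(mean = mu, eigenvalues = ev,
                 whiten = t(V) / d, dewhiten = V * rep(d, each = n), k = k),
            class = "pca_model")
}

#' @rdname pca_model
#' @param model A `pca_model`.
#' @export
pca_project <- function(model, X) {
  model$whiten %*% (as.matrix(X) - model$mean)
}

#' @rdname pca_model
#' @param Y Whitened `k x p` matrix.
#' @export
pca_backproject <- function(model, Y) {
  model$dewhiten %*% Y + model$mean
}

#' Elbow-based component-count selection
#'
#' Returns the index of maximum perpendicular distance from the normalized
#' eigenvalue curve to the chord joining its endpoints; a supplied override
#' (e.g., a count fixed a priori) short-circuits the search. A numerically
#' flat spectrum (degenerate chord) yields 1 with a warning.
#'
#' @param eigenvalues Positive, non-increasing numeric vector (length >= 3).
#' @param override Optional integer returned as-is.
#' @return Integer component count.
#' @export
select_components_elbow <- function(eigenvalues, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 3L || any(ev <= 0)) {
    lf_stop("need at least 3 positive eigenvalues", "longfuse_config_error")
  }
  if (any(diff(ev) > 1e-10 * max(ev))) {
    lf_stop("eigenvalues must be non-increasing", "longfuse_config_error")
  }
  m <- length(ev)
  x <- (seq_len(m) - 1) / (m - 1)
  rng <- max(ev) - min(ev)
  if (rng <= 1e-12 * max(ev)) {
    warning("flat eigenvalue spectrum; returning 1 component")
    return(1L)
  }
  y <- (ev - min(ev)) / rng
  # distance from (x, y) to the chord from (0, y[1]) to (1, y[m])
  dx <- 1; dy <- y[m] - y[1]
  dist <- abs(dy * x - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  if (max(dist) < 1e-8) {
    warning("spectrum is linear; elbow undefined, returning 1 component")
    return(1L)
  }
  which.max(dist)
}

#' Construct a fusion result container
#'
#' @param loadings Named list of `n_subjects x k` loading matrices.
#' @param sources Named list of `k x n_features` source matrices (matching
#'   names).
#' @param canonical_correlations Optional length-`k` vector (symmetric arm).
#' @param iterations,converged,seed,k,method,info Metadata.
#' @return An object of class `fusion_result`.
#' @export
fusion_result <- function(loadings, sources, canonical_correlations = NULL,
                          iterations = NA_integer_, converged = NA,
                          seed = NA_integer_, k, method, info = list()) {
  stopifnot(identical(names(loadings), names(sources)))
  structure(list(loadings = loadings, sources = sources,
                 canonical_correlations = canonical_correlations,
                 iterations = iterations, converged = converged,
                 seed = seed, k = k, method = method, info = info),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result (%s): k = %d, modalities: %s\n", x$method, x$k,
              paste(names(x$loadings), collapse = ", ")))
  cat(sprintf("  converged = %s after %s iterations (seed %s)\n",
              x$converged, x$iterations, x$seed))
  if (!is.null(x$canonical_correlations)) {
    cat("  canonical correlations:",
        paste(sprintf("%.3f", x$canonical_correlations), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Infomax independent component analysis
#'
#' Decomposes `X ~ A S` with maximally independent source rows: the data are
#' reduced to `k` dimensions by PCA whitening over rows, then an unmixing
#' matrix is estimated by full-batch natural-gradient ascent of the infomax
#' objective with a logistic nonlinearity. The mixing matrix is recovered
#' through the de-whitening transform. Convergence is declared when the
#' largest absolute weight update falls below `tol`; on divergence the
#' learning rate is annealed by `anneal` and the step retried.
#'
#' @param X `n x p` matrix (e.g., subjects x features); a `delta_matrix` is
#'   accepted.
#' @param k Number of components (`k < n`, `k <= p`).
#' @param seed Integer seed for the random orthogonal initialization.
#' @param learning_rate,anneal,grow,max_rate,tol,max_iter Optimizer
#'   settings: the learning rate starts at `learning_rate`, grows gently by
#'   factor `grow` per accepted step up to `max_rate`, and is annealed by
#'   `anneal` (with the step retried) when an update diverges.
#' @param center Row-center before whitening (default TRUE).
#' @param modality Name used for the loading/source slots (default "fnc").
#' @return A [fusion_result()] with `A` (`n x k`) and `S` (`k x p`) such that
#'   the centered `X` is approximately `A %*% S`.
#' @export
infomax_ica <- function(X, k, seed = 1L, learning_rate = 0.01, anneal = 0.9,
                        grow = 1.02, max_rate = 0.1, tol = 1e-6,
                        max_iter = 2048L, center = TRUE,
                        modality = "fnc") {
  X <- lf_delta_data(X)
  n <- nrow(X); p <- ncol(X)
  if (n < k) lf_stop("need at least k rows", "longfuse_config_error")
  if (p < k) lf_stop("need at least k features", "longfuse_config_error")
  pm <- pca_model(X, k, center = center)
  Y <- pca_project(pm, X)                       # k x p, identity covariance
  set.seed(lf_seed(seed))
  W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  I_k <- diag(k)
  lr <- learning_rate
  converged <- FALSE
  it <- 0L
  prev_step <- Inf
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Y
    g <- 1 / (1 + exp(-U))
    grad <- I_k + tcrossprod(1 - 2 * g, U) / p
    W_new <- W + lr * grad %*% W
    step <- max(abs(W_new - W))
    if (!all(is.finite(W_new)) ||
        (it > 5L && step > 5 * prev_step && step > 0.05)) {
      lr <- lr * anneal                         # diverged: anneal and retry
      next
    }
    W <- W_new
    prev_step <- step
    if (step < tol) { converged <- TRUE; break }
    lr <- min(lr * grow, max_rate)
  }
  if (!converged) {
    warning(sprintf("infomax ICA did not reach tol = %g in %d iterations",
                    tol, max_iter))
  }
  S <- W %*% Y
  A <- pm$dewhiten %*% solve(W)
  res <- fusion_result(
    loadings = stats::setNames(list(A), modality),
    sources = stats::setNames(list(S), modality),
    iterations = it, converged = converged, seed = as.integer(seed), k = k,
    method = "infomax_ica",
    info = list(pca = pm, learning_rate = learning_rate, tol = tol))
  fix_signs_and_order(res)
}

# internal: whiten the column space of a subjects x p matrix into n x r
# orthonormal scores (unit variance). r = full numerical rank unless
# `reduce` asks for a PCA cut; always >= k canonical dimensions required.
lf_cca_prep <- function(Y, k, reduce = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  sv <- svd(Yc)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (!is.null(reduce)) r <- min(r, as.integer(reduce))
  r <- as.integer(r)
  if (r < k) {
    lf_stop("a data set has rank < k; choose a smaller k",
            "longfuse_config_error")
  }
  list(Z = sv$u[, seq_len(r), drop = FALSE] * sqrt(n - 1), Yc = Yc,
       d = sv$d, r = r)
}

#' Multiset canonical correlation analysis (SSQCOR)
#'
#' Stage-wise maximization of the sum of squared pairwise correlations
#' between same-index canonical variates across data sets, with successive
#' variates orthogonal within each set. Each set is first PCA-reduced to `k`
#' whitened scores. For exactly two sets the solution coincides with
#' classical CCA.
#'
#' @param Y_list List of `n x p_k` matrices sharing the subject dimension.
#' @param k Number of canonical variates.
#' @param reduce Optional per-set PCA depth applied before the canonical
#'   analysis (the fusion pipeline uses `reduce = k`); default `NULL` keeps
#'   the full numerical rank, in which case the two-set solution coincides
#'   with classical CCA of the original data.
#' @param max_iter,tol Inner alternating-maximization controls.
#' @return List with `variates` (per set, `n x k`), `maps` (per set,
#'   `k x p_k`, the least-squares source maps `pinv(D) X`),
#'   `canonical_correlations` (root-mean squared pairwise correlation per
#'   index, non-increasing), and `weights`.
#' @export
mcca <- function(Y_list, k, reduce = NULL, max_iter = 200L, tol = 1e-12) {
  stopifnot(is.list(Y_list), length(Y_list) >= 2L)
  n <- nrow(Y_list[[1L]])
  for (Y in Y_list) {
    if (nrow(Y) != n) lf_stop("all sets must share the subject dimension",
                              "longfuse_config_error")
  }
  K <- length(Y_list)
  prep <- lapply(Y_list, lf_cca_prep, k = k, reduce = reduce)
  Z <- lapply(prep, `[[`, "Z")
  rr <- vapply(prep, `[[`, integer(1), "r")
  # cross-correlation matrices between whitened scores
  R <- vector("list", K)
  for (a in seq_len(K)) {
    R[[a]] <- vector("list", K)
    for (b in seq_len(K)) {
      if (a != b) R[[a]][[b]] <- crossprod(Z[[a]], Z[[b]]) / (n - 1)
    }
  }
  W <- lapply(seq_len(K), function(a) matrix(0, rr[a], k))  # weight columns
  n_pairs <- K * (K - 1) / 2
  ccs <- numeric(k)
  for (s in seq_len(k)) {
    # orthogonal-complement projectors given previous stages
    P <- lapply(seq_len(K), function(a) {
      if (s == 1L) diag(rr[a]) else {
        Wp <- W[[a]][, seq_len(s - 1L), drop = FALSE]
        diag(rr[a]) - tcrossprod(Wp)
      }
    })
    # init: leading eigenvector of sum_l R_al R_la in the allowed subspace
    w <- lapply(seq_len(K), function(a) {
      M <- matrix(0, rr[a], rr[a])
      for (b in seq_len(K)) if (b != a) M <- M + tcrossprod(R[[a]][[b]])
      M <- P[[a]] %*% M %*% P[[a]]
      v <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1L]
      v / sqrt(sum(v^2))
    })
    obj_old <- -Inf
    for (iter in seq_len(max_iter)) {
      for (a in seq_len(K)) {
        Cm <- vapply(setdiff(seq_len(K), a),
                     function(b) drop(R[[a]][[b]] %*% w[[b]]),
                     numeric(rr[a]))
        Cm <- matrix(Cm, nrow = rr[a])
        M <- P[[a]] %*% tcrossprod(Cm) %*% P[[a]]
        v <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1L]
        nv <- sqrt(sum(v^2))
        if (nv > 0) w[[a]] <- v / nv
      }
      obj <- 0
      for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
        obj <- obj + drop(crossprod(w[[a]], R[[a]][[b]] %*% w[[b]]))^2
      }
      if (abs(obj - obj_old) < tol) break
      obj_old <- obj
    }
    # canonical sign convention: each set's variate correlates positively
    # with the first set's variate at the same index
    for (b in seq_len(K)[-1L]) {
      if (drop(crossprod(w[[1L]], R[[1L]][[b]] %*% w[[b]])) < 0) {
        w[[b]] <- -w[[b]]
      }
    }
    for (a in seq_len(K)) W[[a]][, s] <- w[[a]]
    ccs[s] <- sqrt(obj / n_pairs)
  }
  variates <- lapply(seq_len(K), function(a) Z[[a]] %*% W[[a]])
  maps <- lapply(seq_len(K), function(a) {
    D <- variates[[a]]
    solve(crossprod(D), crossprod(D, prep[[a]]$Yc))
  })
  nm <- names(Y_list)
  if (!is.null(nm)) {
    names(variates) <- names(maps) <- nm
  }
  list(variates = variates, maps = maps, canonical_correlations = ccs,
       weights = W)
}

#' Normalize a feature matrix before fusion
#'
#' Z-scores each feature column (columns with zero variance are left at
#' zero), then rescales the whole matrix to unit mean sum of squares so that
#' modalities with different feature counts contribute comparably to joint
#' decomposition.
#'
#' @param X Numeric matrix (subjects x features).
#' @return Normalized matrix; attribute `scale` stores the global divisor.
#' @export
normalize_features <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s_raw <- apply(X, 2L, sd)
  s <- s_raw
  s[s == 0 | !is.finite(s)] <- Inf          # zero-variance columns -> 0
  Xn <- sweep(sweep(X, 2L, mu), 2L, s, "/")
  g <- sqrt(mean(Xn^2))
  if (g > 0) Xn <- Xn / g
  attr(Xn, "scale") <- g
  attr(Xn, "col_mean") <- mu
  attr(Xn, "col_sd") <- s_raw
  Xn
}

#' Symmetric multimodal fusion: mCCA followed by joint ICA
#'
#' Pipeline: per-modality feature normalization, PCA reduction to `k`,
#' multiset CCA linking the modalities, horizontal concatenation of the
#' associated maps, and infomax ICA of the concatenated maps. The joint
#' unmixing splits into per-modality sources `S_F`, `S_G`, and each
#' modality obeys its own model `X ~ A S`. Sources are estimated in the
#' normalized feature space (which stabilizes the decomposition) but
#' returned on the raw feature scale, so a source row reads in the units of
#' the input change matrix; loadings are then the least-squares fit of the
#' uncentered raw data on those sources, so a mean change shared across
#' subjects appears as a nonzero loading mean (the quantity the one-sample
#' loading t-test interrogates) rather than being absorbed by centering.
#'
#' @param x_fnc,x_gmv `delta_matrix` objects (or matrices) over the same
#'   subjects in the same order.
#' @param k Components; `NULL` selects the per-modality elbow and takes the
#'   minimum.
#' @param seed Integer seed (ICA initialization).
#' @param ... Passed to [infomax_ica()] (e.g., `tol`, `max_iter`).
#' @return A [fusion_result()] with modalities `fnc` and `gmv`, canonical
#'   correlations, and reconstruction residuals (relative Frobenius error of
#'   `A S` against each normalized modality) in `info$recon_error`.
#' @export
mcca_jica <- function(x_fnc, x_gmv, k = 5L, seed = 1L, ...) {
  XF <- lf_delta_data(x_fnc)
  XG <- lf_delta_data(x_gmv)
  if (nrow(XF) != nrow(XG)) {
    lf_stop("modalities have different subject counts", "longfuse_config_error")
  }
  if (!is.null(rownames(XF)) && !is.null(rownames(XG)) &&
      !identical(rownames(XF), rownames(XG))) {
    lf_stop("subject order differs between modalities",
            "longfuse_config_error")
  }
  XFn <- normalize_features(XF)
  XGn <- normalize_features(XG)
  if (is.null(k)) {
    kF <- select_components_elbow(pca_model(t(XFn), min(dim(XFn)))$eigenvalues)
    kG <- select_components_elbow(pca_model(t(XGn), min(dim(XGn)))$eigenvalues)
    k <- min(kF, kG)
  }
  cc <- mcca(list(fnc = XFn, gmv = XGn), k = k, reduce = k)
  C <- cbind(cc$maps$fnc, cc$maps$gmv)
  pF <- ncol(XFn)
  ica <- infomax_ica(C, k = k, seed = seed, center = FALSE,
                     modality = "joint", ...)
  S <- ica$sources$joint
  B <- ica$loadings$joint                    # k x k joint mixing
  # undo the per-feature normalization: a source row reads in raw units
  S_F <- sweep(S[, seq_len(pF), drop = FALSE], 2L,
               attr(XFn, "col_sd") * attr(XFn, "scale"), "*")
  S_G <- sweep(S[, (pF + 1L):ncol(S), drop = FALSE], 2L,
               attr(XGn, "col_sd") * attr(XGn, "scale"), "*")
  res <- fusion_result(
    loadings = list(fnc = cc$variates$fnc %*% B,
                    gmv = cc$variates$gmv %*% B),
    sources = list(fnc = S_F, gmv = S_G),
    canonical_correlations = cc$canonical_correlations,
    iterations = ica$iterations, converged = ica$converged,
    seed = as.integer(seed), k = k, method = "mcca_jica",
    info = list(norm_scale = c(fnc = attr(XFn, "scale"),
                               gmv = attr(XGn, "scale"))))
  res <- fix_signs_and_order(res)
  # final loadings: least squares of the *uncentered* raw data on the
  # canonical sources, so a shared mean change across subjects shows up as
  # a nonzero loading mean (testable by the one-sample t) instead of being
  # absorbed into centering
  for (m in c("fnc", "gmv")) {
    Xm <- if (m == "fnc") XF else XG
    Sm <- res$sources[[m]]
    A <- t(solve(tcrossprod(Sm), Sm %*% t(Xm)))
    rownames(A) <- rownames(Xm)
    res$loadings[[m]] <- A
  }
  res$info$recon_error <- c(
    fnc = norm(XF - res$loadings$fnc %*% res$sources$fnc, "F") /
      norm(XF, "F"),
    gmv = norm(XG - res$loadings$gmv %*% res$sources$gmv, "F") /
      norm(XG, "F"))
  res
}

#' Canonicalize component signs, scales and order
#'
#' Each component's concatenated source row is sign-flipped so that its
#' largest-magnitude element is positive (the same flip is applied to all
#' modalities, preserving cross-modal loading correlations); per modality,
#' source rows are rescaled to unit norm with the loading column absorbing
#' the scale, so every product `A S` is unchanged. Components are reordered
#' by explained variance in the first modality. Idempotent.
#'
#' @param result A [fusion_result()].
#' @return The canonicalized `fusion_result`.
#' @export
fix_signs_and_order <- function(result) {
  stopifnot(inherits(result, "fusion_result"))
  k <- result$k
  S_cat <- do.call(cbind, result$sources)
  sgn <- vapply(seq_len(k), function(j) {
    v <- S_cat[j, ]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  for (m in names(result$sources)) {
    S <- result$sources[[m]] * sgn
    A <- sweep(result$loadings[[m]], 2L, sgn, "*")
    nrm <- sqrt(rowSums(S^2))
    nrm[nrm == 0] <- 1
    result$sources[[m]] <- S / nrm
    result$loadings[[m]] <- sweep(A, 2L, nrm, "*")
  }
  first <- names(result$loadings)[1L]
  expl <- colSums(result$loadings[[first]]^2)
  ord <- order(expl, decreasing = TRUE)
  for (m in names(result$sources)) {
    result$sources[[m]] <- result$sources[[m]][ord, , drop = FALSE]
    result$loadings[[m]] <- result$loadings[[m]][, ord, drop = FALSE]
  }
  if (!is.null(result$canonical_correlations) &&
      length(result$canonical_correlations) == k) {
    result$canonical_correlations <- result$canonical_correlations[ord]
  }
  result
}

#' Match estimated components to planted sources
#'
#' Greedy one-to-one assignment maximizing the absolute Pearson correlation
#' between estimated and true source rows; used to score recovery on
#' synthetic cohorts.
#'
#' @param S_est,S_true `k x p` matrices.
#' @return Data frame with `est` (estimated index), `truth` (matched planted
#'   index), `r` (signed correlation of the matched pair).
#' @export
match_sources <- function(S_est, S_true) {
  k <- nrow(S_est)
  stopifnot(nrow(S_true) == k, ncol(S_est) == ncol(S_true))
  cm <- cor(t(S_est), t(S_true))
  avail_e <- seq_len(k); avail_t <- seq_len(k)
  out <- data.frame(est = integer(k), truth = integer(k), r = numeric(k))
  for (i in seq_len(k)) {
    sub <- abs(cm[avail_e, avail_t, drop = FALSE])
    idx <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    e <- avail_e[idx[1L]]; t_ <- avail_t[idx[2L]]
    out$est[i] <- e; out$truth[i] <- t_; out$r[i] <- cm[e, t_]
    avail_e <- setdiff(avail_e, e); avail_t <- setdiff(avail_t, t_)
  }
  out[order(out$truth), ]
}

#' Amari index of a separation
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' `W` and a true mixing `A`; 0 means perfect separation, and values below
#' 0.01 indicate essentially exact recovery.
#'
#' @param W Estimated `k x k` unmixing matrix.
#' @param A True `k x k` mixing matrix.
#' @return Nonnegative scalar.
#' @export
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  k <- nrow(P)
  r1 <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  r2 <- sum(colSums(t(t(P) / apply(P, 2L, max))) - 1)
  (r1 + r2) / (2 * k * (k - 1))
}
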