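#' Linear kernel matrix over subject feature maps
#'
#' Features are the in-mask voxels of each subject's (smoothed, modulated)
#' grey-matter or thickness map, mean-centred across subjects; the kernel
#' is `K = F F' / D` with D the voxel count, so entries stay O(1)
#' regardless of mask size.  The centred feature matrix is retained for
#' the voxel-wise weight map.
#'
#' @param feature_maps list of subject [volume]s on one grid
#' @param mask feature mask [volume]
#' @return a `kernel_matrix`: `K` (N x N), `features` (N x D, centred),
#'   `D`, `mask_idx`, `ref`
#' @export
build_linear_kernel <- function(feature_maps, mask) {
  stop_if(length(feature_maps) < 3, "need at least three subjects")
  do.call(check_grid, c(unname(feature_maps), list(mask)))
  idx <- which(mask$data > 0)
  stop_if(length(idx) == 0, "empty feature mask")
  F <- t(vapply(feature_maps, function(m) as.numeric(m$data)[idx],
                numeric(length(idx))))
  F <- sweep(F, 2, colMeans(F))
  K <- tcrossprod(F) / ncol(F)
  structure(list(K = (K + t(K)) / 2, features = F, D = ncol(F),
                 mask_idx = idx, ref = mask, residualised = FALSE),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d subjects, %d features%s\n", nrow(x$K), x$D,
              if (x$residualised) " (confound-residualised)" else ""))
  invisible(x)
}

# residualising projector for a confound matrix (intercept appended)
confound_projector <- function(confounds, n) {
  M <- as.matrix(confounds)
  if (ncol(M) > 0) {
    constant <- apply(M, 2, function(x) stats::sd(x) == 0)
    M <- M[, !constant, drop = FALSE]   # absorbed by the intercept
  }
  C <- cbind(1, M)
  stop_if(nrow(C) != n, "confound rows must match subjects")
  stop_if(qr(C)$rank < ncol(C), "confound matrix is rank deficient")
  diag(n) - C %*% solve(crossprod(C)) %*% t(C)
}

#' Residualise a kernel matrix on confounding variables
#'
#' `K' = R K R` with `R` the residual-forming projector of the confound
#' matrix (intercept appended), i.e. the kernel of the features after
#' removing everything linearly explained by the confounds.  Idempotent.
#'
#' @param kernel a `kernel_matrix` (or plain N x N matrix)
#' @param confounds numeric matrix of confounds (subjects x variables);
#'   `NULL` applies intercept-only double-centring
#' @return residualised `kernel_matrix`
#' @export
residualise_confounds <- function(kernel, confounds = NULL) {
  plain <- !inherits(kernel, "kernel_matrix")
  K <- if (plain) kernel else kernel$K
  n <- nrow(K)
  R <- confound_projector(confounds %||% matrix(nrow = n, ncol = 0), n)
  Kr <- R %*% K %*% R
  Kr <- (Kr + t(Kr)) / 2
  if (plain) return(Kr)
  kernel$K <- Kr
  kernel$features <- R %*% kernel$features
  kernel$residualised <- TRUE
  kernel
}

# profiled GP marginal likelihood on the eigenbasis of K:
# Sigma = th_s K + th_n I = th_s (K + rho I); th_s has a closed form
gp_profile_fit <- function(lambda, ytil, log_rho_range = c(-8, 8)) {
  N <- length(ytil)
  nll <- function(lr) {
    rho <- exp(lr)
    m <- lambda + rho
    q <- sum(ytil^2 / m)
    ths <- max(q / N, 1e-12)
    0.5 * (N + N * log(ths) + sum(log(m)) + N * log(2 * pi))
  }
  opt <- stats::optimize(nll, log_rho_range)
  rho <- exp(opt$minimum)
  m <- lambda + rho
  q <- sum(ytil^2 / m)
  ths <- max(q / N, 1e-12)
  list(theta_s = ths, theta_n = ths * rho, rho = rho, lml = -opt$objective)
}

#' Fit a Gaussian-process regression model on a kernel matrix
#'
#' Covariance `Sigma = theta_s K + theta_n I`; the hyperparameters
#' maximise the Gaussian-process log marginal likelihood, profiled over
#' the signal scale (the noise-to-signal ratio is optimised on a log
#' grid), after removing the target mean as an offset.  The dual weights
#' `alpha = Sigma^-1 (y - offset)` are stored.
#'
#' @param kernel a `kernel_matrix` or plain N x N PSD matrix
#' @param y numeric target vector
#' @return a `gpr_model`
#' @export
gpr_fit <- function(kernel, y) {
  K <- if (inherits(kernel, "kernel_matrix")) kernel$K else kernel
  N <- nrow(K)
  stop_if(length(y) != N, "target length mismatch")
  stop_if(N < 3, "need at least three subjects")
  stop_if(!all(is.finite(y)), "targets must be finite")
  eg <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  offset <- mean(y)
  ytil <- as.numeric(crossprod(eg$vectors, y - offset))
  fit <- gp_profile_fit(lambda, ytil)
  alpha <- eg$vectors %*% (ytil / (fit$theta_s * (lambda + fit$rho)))
  structure(list(theta_s = fit$theta_s, theta_n = fit$theta_n,
                 alpha = as.numeric(alpha), offset = offset, lml = fit$lml,
                 K = K,
                 kernel = if (inherits(kernel, "kernel_matrix")) kernel else NULL),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf("gpr_model: %d subjects | signal %.4g, noise %.4g | log marginal likelihood %.2f\n",
              length(x$alpha), x$theta_s, x$theta_n, x$lml))
  invisible(x)
}

#' @export
coef.gpr_model <- function(object, ...) {
  c(theta_s = object$theta_s, theta_n = object$theta_n, offset = object$offset)
}

#' Predict targets from cross-covariance rows
#' @param object a `gpr_model`
#' @param k_new matrix of kernel rows between new and training subjects
#'   (new x train); defaults to the training kernel (fitted values)
#' @param ... unused
#' @export
predict.gpr_model <- function(object, k_new = NULL, ...) {
  k_new <- k_new %||% object$K
  as.numeric(object$theta_s * (k_new %*% object$alpha)) + object$offset
}

#' Precompute leave-one-out fold structures for a fixed kernel
#'
#' For every held-out subject: the training-fold confound projector, the
#' residualised training kernel and its eigendecomposition, and the
#' residualised cross-covariance row of the held-out subject (computed
#' from training-fold statistics only, so no information leaks from the
#' test subject's confounds into the fold kernel).  Re-used across
#' permutations, where only the targets change.
#'
#' @param K N x N kernel matrix
#' @param confounds optional confound matrix
#' @return list of fold structures
#' @keywords internal
loo_cache <- function(K, confounds = NULL) {
  N <- nrow(K)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    keep <- apply(confounds, 2, function(x) stats::sd(x) > 0)
    confounds <- confounds[, keep, drop = FALSE]
    if (ncol(confounds) == 0) confounds <- NULL
  }
  lapply(seq_len(N), function(i) {
    tr <- setdiff(seq_len(N), i)
    Ktr <- K[tr, tr]
    kstar <- K[tr, i]
    if (!is.null(confounds)) {
      Cf <- as.matrix(confounds)
      Ct <- cbind(1, Cf[tr, , drop = FALSE])
      G <- solve(crossprod(Ct))
      R <- diag(N - 1) - Ct %*% G %*% t(Ct)
      cstar <- c(1, Cf[i, ])
      kstar <- as.numeric(R %*% (kstar - Ktr %*% (Ct %*% (G %*% cstar))))
      Ktr <- R %*% Ktr %*% R
      Ktr <- (Ktr + t(Ktr)) / 2
    }
    eg <- eigen(Ktr, symmetric = TRUE)
    list(tr = tr, U = eg$vectors, lambda = pmax(eg$values, 0),
         kstar_rot = as.numeric(crossprod(eg$vectors, kstar)))
  })
}

# one LOO pass over precomputed folds for a given target vector
loo_predict <- function(cache, y) {
  vapply(seq_along(cache), function(i) {
    f <- cache[[i]]
    ytr <- y[f$tr]
    off <- mean(ytr)
    ytil <- as.numeric(crossprod(f$U, ytr - off))
    fit <- gp_profile_fit(f$lambda, ytil)
    alpha_rot <- ytil / (fit$theta_s * (f$lambda + fit$rho))
    fit$theta_s * sum(f$kstar_rot * alpha_rot) + off
  }, 0)
}

#' Leave-one-out cross-validated prediction
#'
#' For each subject the confound projector, kernel eigenstructure and GP
#' hyperparameters are re-estimated on the remaining N-1 subjects and the
#' held-out target predicted through the residualised cross-covariance
#' row.  Quality is summarised by Pearson r, r^2 and RMSE in target units.
#'
#' @param kernel a `kernel_matrix` or plain N x N matrix (not yet
#'   residualised; pass `confounds` here)
#' @param y targets (e.g. WMH volume in mm^3)
#' @param confounds optional confound matrix (subjects x variables)
#' @return a `prediction_report`: `predictions`, `pearson_r`, `r_squared`,
#'   `rmse`, `constant_target` flag
#' @export
loo_cv <- function(kernel, y, confounds = NULL) {
  K <- if (inherits(kernel, "kernel_matrix")) kernel$K else kernel
  N <- nrow(K)
  stop_if(N < 4, "leave-one-out needs at least four subjects")
  cache <- loo_cache(K, confounds)
  pred <- loo_predict(cache, y)
  constant <- stats::sd(y) == 0
  r <- if (constant || stats::sd(pred) == 0) 0 else stats::cor(pred, y)
  structure(list(predictions = pred, observed = y, pearson_r = r,
                 r_squared = r^2, rmse = sqrt(mean((pred - y)^2)),
                 constant_target = constant || stats::sd(pred) == 0),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("LOO prediction: r = %.3f, r^2 = %.3f, RMSE = %.0f%s\n",
              x$pearson_r, x$r_squared, x$rmse,
              if (!is.null(x$permutation_p)) sprintf(", permutation p = %.4g", x$permutation_p) else ""))
  invisible(x)
}

#' Permutation test of the LOO correlation
#'
#' Permutes the targets, reruns the full leave-one-out analysis (fold
#' structures are reusable because the kernel and confounds are fixed) and
#' reports `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @param kernel kernel matrix (see [loo_cv()])
#' @param y targets
#' @param confounds optional confound matrix
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed
#' @return list: `p`, `r_obs`, `r_perm`
#' @export
permutation_significance <- function(kernel, y, confounds = NULL,
                                     n_perm = 1000, seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  K <- if (inherits(kernel, "kernel_matrix")) kernel$K else kernel
  cache <- loo_cache(K, confounds)
  safe_r <- function(p, yy) {
    if (stats::sd(p) == 0 || stats::sd(yy) == 0) 0 else stats::cor(p, yy)
  }
  r_obs <- safe_r(loo_predict(cache, y), y)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    safe_r(loo_predict(cache, yp), yp)
  }, 0))
  list(p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1), r_obs = r_obs,
       r_perm = r_perm)
}

#' Voxel-wise weight map of a fitted linear-kernel GP
#'
#' Primal weights `w = F' alpha / D` mapped back onto the feature mask.
#' The map shows where grey matter drives the prediction but, like any
#' multivariate weight image, individual voxels cannot be interpreted in
#' isolation.
#'
#' @param model a `gpr_model` fitted on a `kernel_matrix` that retained
#'   its features
#' @param kernel optionally, the `kernel_matrix` (defaults to the one
#'   stored in the model)
#' @return weight [volume]
#' @export
weight_map <- function(model, kernel = NULL) {
  kernel <- kernel %||% model$kernel
  stop_if(is.null(kernel) || !inherits(kernel, "kernel_matrix"),
          "a kernel_matrix with stored features is required")
  w <- as.numeric(crossprod(kernel$features, model$alpha)) / kernel$D
  d <- dim(kernel$ref$data)
  a <- array(0, d)
  a[kernel$mask_idx] <- w
  vol_like(kernel$ref, a)
}
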