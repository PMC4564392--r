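#' Build a design matrix from a cohort table
#'
#' Intercept plus the requested covariates; all non-intercept columns are
#' mean-centred so the intercept carries the grand mean.  Sex is coded
#' 0/1.
#'
#' @param table cohort data.frame (one row per subject, in map order)
#' @param covariates column names to include
#' @return numeric matrix with named columns, first column `intercept`
#' @export
design_matrix <- function(table, covariates = c("wmhv_mm3", "age", "sex")) {
  missing_cols <- setdiff(covariates, names(table))
  stop_if(length(missing_cols) > 0,
          paste("missing covariates:", paste(missing_cols, collapse = ", ")))
  M <- as.matrix(table[, covariates, drop = FALSE])
  constant <- apply(M, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    M <- M[, !constant, drop = FALSE]
  }
  X <- cbind(intercept = rep(1, nrow(table)), M)
  for (j in seq_len(ncol(X))[-1]) X[, j] <- X[, j] - mean(X[, j])
  stop_if(qr(X)$rank < ncol(X), "design matrix is rank deficient")
  X
}

#' Voxel-wise ordinary least squares over a set of subject maps
#'
#' @param maps list of [volume]s, one per design row, on one grid
#' @param design numeric design matrix (subjects x regressors)
#' @param mask analysis mask [volume]
#' @return a `glm_result` holding per-voxel coefficients, residual
#'   variance, residuals, the error degrees of freedom and the design
#' @export
fit_glm <- function(maps, design, mask) {
  N <- length(maps)
  stop_if(nrow(design) != N, "one map per design row required")
  do.call(check_grid, c(unname(maps), list(mask)))
  X <- as.matrix(design)
  p <- ncol(X)
  stop_if(qr(X)$rank < p, "design matrix is rank deficient")
  df <- N - p
  stop_if(df <= 0, "no error degrees of freedom")
  idx <- which(mask$data > 0)
  Y <- vapply(maps, function(m) as.numeric(m$data)[idx], numeric(length(idx)))
  Y <- t(Y)                                   # N x n_vox
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% crossprod(X, Y)          # p x n_vox
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / df
  structure(list(beta = beta, sigma2 = sigma2, resid = resid, df = df,
                 X = X, XtXinv = XtXinv, mask_idx = idx, ref = mask,
                 regressors = colnames(X)),
            class = "glm_result")
}

#' t-statistic map for a contrast
#'
#' `t = c'b / sqrt(s^2 c'(X'X)^-1 c)` per voxel; voxels with zero residual
#' variance get t = 0 and their count is recorded in the `n_zero_variance`
#' attribute.
#'
#' @param glm a `glm_result`
#' @param contrast numeric contrast vector (length = regressor count)
#' @param name optional contrast label
#' @return a `t_map`: list with `vol` (statistic [volume]), `df`,
#'   `contrast`, and slots for the smoothness estimate
#' @export
t_contrast <- function(glm, contrast, name = NULL) {
  stopifnot(inherits(glm, "glm_result"))
  stop_if(length(contrast) != ncol(glm$X), "contrast length mismatch")
  stop_if(all(contrast == 0), "contrast must be non-zero")
  cb <- as.numeric(crossprod(contrast, glm$beta))
  vc <- as.numeric(t(contrast) %*% glm$XtXinv %*% contrast)
  se <- sqrt(glm$sigma2 * vc)
  tval <- ifelse(se > 0, cb / se, 0)
  d <- dim(glm$ref$data)
  a <- array(0, d)
  a[glm$mask_idx] <- tval
  structure(list(vol = vol_like(glm$ref, a), df = glm$df,
                 contrast = name %||% paste(contrast, collapse = ","),
                 fwhm_mm = NULL, resels = NULL,
                 mask_idx = glm$mask_idx),
            class = "t_map",
            n_zero_variance = sum(se == 0))
}

#' Estimate residual-field smoothness and resel counts
#'
#' Per-axis FWHM from the variance of the spatial derivatives of the
#' normalised residual fields (the standard random-field smoothness
#' estimator), plus the resolution-element (resel) counts of the analysis
#' mask at that smoothness, computed from the mask's point/edge/face/cube
#' counts.
#'
#' @param glm a `glm_result`
#' @return list `fwhm_mm` (length 3) and `resels` (R0..R3)
#' @export
estimate_smoothness <- function(glm) {
  stopifnot(inherits(glm, "glm_result"))
  d <- dim(glm$ref$data)
  vs <- voxel_size(glm$ref)
  mask <- array(FALSE, d); mask[glm$mask_idx] <- TRUE
  rss <- colSums(glm$resid^2)
  ok <- rss > 0
  V <- numeric(3)
  nvalid <- numeric(3)
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  U <- glm$resid
  U[, ok] <- sweep(U[, ok, drop = FALSE], 2, sqrt(rss[ok]), `/`)
  for (i in seq_len(nrow(U))) {
    u <- array(0, d); u[glm$mask_idx] <- U[i, ]
    for (ax in 1:3) {
      o <- offs[[ax]]
      nb <- shift3(u, -o[1], -o[2], -o[3])
      valid <- mask & shift3(mask * 1, -o[1], -o[2], -o[3]) > 0
      dif <- (nb - u)[valid]
      V[ax] <- V[ax] + sum(dif^2)
      if (i == 1) nvalid[ax] <- sum(valid)
    }
  }
  V <- V / nvalid
  fwhm_vox <- sqrt(4 * log(2) / pmax(V, 1e-12))
  fwhm_mm <- fwhm_vox * vs
  list(fwhm_mm = fwhm_mm, resels = resel_counts(mask, vs / fwhm_mm))
}

# resel counts from mask geometry; r = voxel size / FWHM per axis
resel_counts <- function(mask, r) {
  m <- mask * 1
  Ex <- sum(m * shift3(m, -1, 0, 0))
  Ey <- sum(m * shift3(m, 0, -1, 0))
  Ez <- sum(m * shift3(m, 0, 0, -1))
  Fxy <- sum(m * shift3(m, -1, 0, 0) * shift3(m, 0, -1, 0) * shift3(m, -1, -1, 0))
  Fxz <- sum(m * shift3(m, -1, 0, 0) * shift3(m, 0, 0, -1) * shift3(m, -1, 0, -1))
  Fyz <- sum(m * shift3(m, 0, -1, 0) * shift3(m, 0, 0, -1) * shift3(m, 0, -1, -1))
  C <- sum(m * shift3(m, -1, 0, 0) * shift3(m, 0, -1, 0) * shift3(m, 0, 0, -1) *
             shift3(m, -1, -1, 0) * shift3(m, -1, 0, -1) * shift3(m, 0, -1, -1) *
             shift3(m, -1, -1, -1))
  P <- sum(m)
  R0 <- P - Ex - Ey - Ez + Fxy + Fxz + Fyz - C
  R1 <- (Ex - Fxy - Fxz + C) * r[1] + (Ey - Fxy - Fyz + C) * r[2] +
    (Ez - Fxz - Fyz + C) * r[3]
  R2 <- (Fxy - C) * r[1] * r[2] + (Fxz - C) * r[1] * r[3] + (Fyz - C) * r[2] * r[3]
  R3 <- C * r[1] * r[2] * r[3]
  c(R0 = R0, R1 = R1, R2 = R2, R3 = R3)
}

# Euler-characteristic densities of a t-field, orders 0..3
ec_density_t <- function(t, nu) {
  a <- 4 * log(2)
  base <- (1 + t^2 / nu)^(-(nu - 1) / 2)
  rho0 <- stats::pt(t, nu, lower.tail = FALSE)
  rho1 <- sqrt(a) / (2 * pi) * base
  rho2 <- a / (2 * pi)^(3 / 2) *
    exp(lgamma((nu + 1) / 2) - lgamma(nu / 2)) / sqrt(nu / 2) * t * base
  rho3 <- a^(3 / 2) / (2 * pi)^2 * base * ((nu - 1) / nu * t^2 - 1)
  cbind(rho0, rho1, rho2, rho3)
}

#' Expected Euler characteristic of a t-field excursion
#' @param t threshold(s)
#' @param nu error degrees of freedom
#' @param resels resel counts R0..R3
#' @return expected EC at each threshold
#' @export
expected_ec <- function(t, nu, resels) {
  rho <- ec_density_t(t, nu)
  as.numeric(rho %*% resels)
}

#' Peak family-wise-error corrected p-values by random field theory
#'
#' The corrected p at a voxel is the expected Euler characteristic of the
#' t-field excursion set above that voxel's value (Worsley's EC densities
#' for t-fields, orders 0-3), clipped to \[0, 1\].  The smoothness must
#' have been estimated and attached first.
#'
#' @param tmap a `t_map` with `fwhm_mm` and `resels` filled in (see
#'   [estimate_smoothness()])
#' @return [volume] of corrected p-values (1 outside the mask)
#' @export
rft_peak_fwe <- function(tmap) {
  stopifnot(inherits(tmap, "t_map"))
  stop_if(is.null(tmap$resels) || is.null(tmap$df),
          "smoothness/resels missing: run estimate_smoothness first")
  d <- dim(tmap$vol$data)
  p <- array(1, d)
  tv <- tmap$vol$data[tmap$mask_idx]
  ec <- expected_ec(pmax(tv, 0), tmap$df, tmap$resels)
  # the EC approximation is only valid in the upper tail; the corrected p
  # can never undercut the uncorrected p (Bonferroni-like dominance)
  punc <- stats::pt(tv, tmap$df, lower.tail = FALSE)
  pv <- pmin(pmax(ec, punc), 1)
  pv[tv <= 0] <- 1
  p[tmap$mask_idx] <- pv
  vol_like(tmap$vol, p)
}

#' RFT peak-FWE critical threshold at a given alpha
#' @param nu degrees of freedom
#' @param resels resel counts
#' @param alpha family-wise error level
#' @export
rft_threshold <- function(nu, resels, alpha = 0.05) {
  fwe_p <- function(t) pmin(1, pmax(expected_ec(t, nu, resels),
                                    stats::pt(t, nu, lower.tail = FALSE)))
  grid <- seq(0.5, 150, by = 0.5)
  pv <- fwe_p(grid)
  hi <- grid[which(pv <= alpha)[1]]
  if (is.na(hi)) return(Inf)
  stats::uniroot(function(t) fwe_p(t) - alpha, c(hi - 0.5, hi))$root
}

#' Max-statistic permutation FWE p-values (Freedman-Lane)
#'
#' The tested regressor's effect is permuted after residualising the data
#' on the nuisance regressors (Freedman-Lane scheme); the corrected p of a
#' voxel is the fraction of permutations whose maximum t anywhere in the
#' mask reaches that voxel's observed t.  Serves as the assumption-light
#' cross-check of [rft_peak_fwe()].
#'
#' @param maps list of subject [volume]s
#' @param design design matrix
#' @param contrast contrast vector with exactly one non-zero entry
#' @param mask analysis mask [volume]
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @return list: `p` ([volume] of FWE p), `max_t` (null max-t draws),
#'   `t_obs` (`t_map`)
#' @export
permutation_maxT <- function(maps, design, contrast, mask, n_perm = 1000,
                             seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  tested <- which(contrast != 0)
  stop_if(length(tested) != 1, "contrast must select a single regressor")
  glm <- fit_glm(maps, design, mask)
  tobs <- t_contrast(glm, contrast)
  X <- glm$X
  N <- nrow(X)
  Z <- X[, -tested, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Y <- vapply(maps, function(m) as.numeric(m$data)[glm$mask_idx],
              numeric(length(glm$mask_idx)))
  Y <- t(Y)
  Rz_Y <- Y - Hz %*% Y
  Hz_Y <- Y - Rz_Y
  XtXinv <- glm$XtXinv
  vc <- as.numeric(t(contrast) %*% XtXinv %*% contrast)
  tstat <- function(Yp) {
    beta <- XtXinv %*% crossprod(X, Yp)
    resid <- Yp - X %*% beta
    sigma2 <- colSums(resid^2) / glm$df
    cb <- as.numeric(crossprod(contrast, beta))
    se <- sqrt(sigma2 * vc)
    ifelse(se > 0, cb / se, 0)
  }
  max_t <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(N)
    max(tstat(Rz_Y[perm, , drop = FALSE] + Hz_Y))
  }, 0))
  tv <- tobs$vol$data[glm$mask_idx]
  pv <- vapply(tv, function(t0) (1 + sum(max_t >= t0)) / (n_perm + 1), 0)
  d <- dim(mask$data)
  p <- array(1, d)
  p[glm$mask_idx] <- pv
  list(p = vol_like(mask, p), max_t = max_t, t_obs = tobs)
}
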