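#' Named set of tissue probability maps
#'
#' An ordered, named collection of probability volumes (e.g. `gm`, `wm`,
#' `csf`, optionally `wmh`) on a shared grid.  Per-voxel class sums may not
#' exceed 1 (+1e-4); each map lies in \[0, 1\].
#'
#' @param maps named list of probability [volume]s
#' @return a `tpm_set`
#' @export
tpm_set <- function(maps) {
  stop_if(is.null(names(maps)) || any(names(maps) == ""),
          "tissue maps must be named")
  do.call(check_grid, unname(maps))
  tot <- 0
  for (m in maps) {
    stop_if(min(m$data) < -1e-6 || max(m$data) > 1 + 1e-6,
            "probability map outside [0, 1]")
    tot <- tot + m$data
  }
  stop_if(max(tot) > 1 + 1e-4, "per-voxel class probabilities sum to > 1")
  structure(list(maps = maps), class = "tpm_set")
}

#' @export
print.tpm_set <- function(x, ...) {
  d <- dim(x$maps[[1]]$data)
  cat(sprintf("tpm_set: classes {%s} on %d x %d x %d grid\n",
              paste(names(x$maps), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

# stack in-mask channel intensities into an n x C matrix
channel_matrix <- function(channels, idx) {
  vapply(channels, function(ch) as.numeric(ch$data)[idx], numeric(length(idx)))
}

# log bivariate/multivariate normal density, vectorised over rows of X
log_mvn <- function(X, mu, Sigma) {
  C <- ncol(X)
  L <- chol(Sigma)
  xc <- sweep(X, 2, mu)
  z <- t(backsolve(L, t(xc), transpose = TRUE))
  -0.5 * rowSums(z^2) - sum(log(diag(L))) - 0.5 * C * log(2 * pi)
}

#' Fit a (prior-weighted) multivariate mixture of Gaussians by EM
#'
#' Expectation-maximisation over the in-mask voxels of one or more image
#' channels.  When a set of prior tissue probability maps is supplied, the
#' per-voxel prior probabilities act as the mixing weights in the E-step
#' (the "population-prior-weighted" variant used for cohort-specific
#' segmentation); otherwise global mixing weights are estimated.  The
#' log-likelihood is checked to be non-decreasing at every iteration, and
#' covariances are regularised by a small ridge.
#'
#' @param channels list of [volume]s (e.g. T1, FLAIR) on one grid
#' @param mask binary mask [volume] of voxels to fit
#' @param priors optional [tpm_set] with one map per class
#' @param K number of classes (ignored when `priors` is given)
#' @param seed seed for the k-means initialisation
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` or `max_iter` iterations
#' @param init_means optional K x channels matrix of starting means
#'   (bypasses the k-means initialisation; needed when a class of interest
#'   is too rare for clustering to find, e.g. a lesion class)
#' @param init_covs optional list of K starting covariance matrices
#' @return a `mixture_model`: class means, covariances, mixing weights,
#'   class names and the log-likelihood trace
#' @export
fit_mixture <- function(channels, mask, priors = NULL, K = 3, seed = 1L,
                        max_iter = 200L, tol = 1e-6, init_means = NULL,
                        init_covs = NULL) {
  stop_if(length(channels) < 1, "need at least one channel")
  do.call(check_grid, c(unname(channels), list(mask)))
  idx <- which(mask$data > 0)
  stop_if(length(idx) == 0, "empty mask")
  X <- channel_matrix(channels, idx)
  C <- ncol(X)
  if (!is.null(priors)) {
    stopifnot(inherits(priors, "tpm_set"))
    K <- length(priors$maps)
    P <- vapply(priors$maps, function(m) as.numeric(m$data)[idx],
                numeric(length(idx)))
    P <- pmax(P, 1e-6)
    P <- P / rowSums(P)
  } else {
    P <- NULL
  }
  stop_if(K < 2, "K must be >= 2")
  stop_if(nrow(unique(round(X, 8))) < K,
          "fewer distinct intensity vectors than classes: degenerate fit")
  if (!is.null(init_means)) {
    mu <- as.matrix(init_means)
    stop_if(nrow(mu) != K || ncol(mu) != C, "init_means must be K x channels")
  } else if (!is.null(P)) {
    # priors identify the classes, so initialise from prior-weighted moments
    mu <- matrix(vapply(seq_len(K), function(k)
      colSums(X * P[, k]) / max(sum(P[, k]), 1e-9), numeric(C)),
      nrow = K, byrow = TRUE)
  } else {
    # k-means initialisation on a subsample
    km <- with_seed(seed, {
      sub <- if (nrow(X) > 20000) X[sample.int(nrow(X), 20000), , drop = FALSE] else X
      tryCatch(stats::kmeans(sub, centers = K, nstart = 3, iter.max = 100),
               error = function(e) stop("degenerate fit: ", conditionMessage(e), call. = FALSE))
    })
    ord <- order(km$centers[, 1])
    mu <- km$centers[ord, , drop = FALSE]
  }
  covs <- if (is.null(init_covs) && !is.null(P)) {
    # prior-weighted within-class second moments
    lapply(seq_len(K), function(k) {
      xc <- sweep(X, 2, mu[k, ])
      crossprod(xc * sqrt(P[, k])) / max(sum(P[, k]), 1e-9) + diag(1e-6, C)
    })
  } else if (is.null(init_covs)) {
    rep(list(stats::cov(X) / K + diag(1e-6, C)), K)
  } else {
    stop_if(length(init_covs) != K, "init_covs must list K matrices")
    lapply(init_covs, function(S) S + diag(1e-6, C))
  }
  w <- rep(1 / K, K)
  ridge <- diag(1e-6 * mean(apply(X, 2, stats::var)) + 1e-10, C)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k) log_mvn(X, mu[k, ], covs[[k]]),
                   numeric(nrow(X)))
    logw <- if (is.null(P)) matrix(log(w), nrow(X), K, byrow = TRUE) else log(P)
    lj <- logd + logw
    m <- apply(lj, 1, max)
    pj <- exp(lj - m)
    sj <- rowSums(pj)
    ll <- sum(m + log(sj))
    stop_if(ll < ll_prev - abs(ll_prev) * 1e-8 - 1e-8,
            "EM log-likelihood decreased; numerical failure")
    ll_trace <- c(ll_trace, ll)
    gamma <- pj / sj
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
    nk <- colSums(gamma)
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(gamma[, k] * X) / nk[k]
      xc <- sweep(X, 2, mu[k, ])
      covs[[k]] <- crossprod(xc * sqrt(gamma[, k])) / nk[k] + ridge
    }
    if (is.null(P)) w <- nk / nrow(X)
  }
  cls <- if (!is.null(priors)) names(priors$maps) else paste0("class", seq_len(K))
  structure(list(K = K, means = mu, covs = covs, weights = w,
                 class_names = cls,
                 channel_names = names(channels) %||% paste0("ch", seq_len(C)),
                 loglik = ll_trace,
                 converged = length(ll_trace) < max_iter),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: %d classes x %d channels, final log-likelihood %.2f (%d EM iterations)\n",
              x$K, ncol(x$means), utils::tail(x$loglik, 1), length(x$loglik)))
  print(round(x$means, 2))
  invisible(x)
}

#' Posterior tissue probability maps under a fitted mixture model
#'
#' Per-voxel class responsibilities; with priors supplied these act as the
#' per-voxel mixing weights.  In-mask posteriors sum to 1; voxels outside
#' the mask are 0.
#'
#' @param model a `mixture_model`
#' @param channels list of [volume]s matching the model's channels
#' @param priors optional [tpm_set] of per-voxel priors
#' @param mask binary mask [volume]
#' @return a [tpm_set] of posterior maps
#' @export
posterior_maps <- function(model, channels, priors = NULL, mask) {
  stopifnot(inherits(model, "mixture_model"))
  stop_if(length(channels) != ncol(model$means),
          "channel count does not match the fitted model")
  do.call(check_grid, c(unname(channels), list(mask)))
  idx <- which(mask$data > 0)
  X <- channel_matrix(channels, idx)
  K <- model$K
  if (!is.null(priors)) {
    P <- vapply(priors$maps, function(m) as.numeric(m$data)[idx],
                numeric(length(idx)))
    P <- pmax(P, 1e-6); P <- P / rowSums(P)
    logw <- log(P)
  } else {
    logw <- matrix(log(model$weights), nrow(X), K, byrow = TRUE)
  }
  logd <- vapply(seq_len(K), function(k) log_mvn(X, model$means[k, ], model$covs[[k]]),
                 numeric(nrow(X)))
  lj <- logd + logw
  m <- apply(lj, 1, max)
  pj <- exp(lj - m)
  gamma <- pj / rowSums(pj)
  d <- dim(mask$data)
  maps <- lapply(seq_len(K), function(k) {
    a <- array(0, d)
    a[idx] <- gamma[, k]
    vol_like(mask, a)
  })
  tpm_set(stats::setNames(maps, model$class_names))
}

#' Population tissue probability maps from per-subject segmentations
#'
#' Voxel-wise class means over subjects in group space, smoothed, floored
#' by a small epsilon inside the brain so no class ever has a zero prior,
#' and renormalised to sum to at most 1.
#'
#' @param subject_tpms list of [tpm_set]s on the group grid
#' @param smooth_fwhm_mm smoothing applied to the averaged maps
#' @param eps prior floor inside the brain
#' @return a [tpm_set] of population priors
#' @export
build_population_tpms <- function(subject_tpms, smooth_fwhm_mm = 4, eps = 1e-3) {
  stop_if(length(subject_tpms) < 2, "need at least two subjects")
  classes <- names(subject_tpms[[1]]$maps)
  ref <- subject_tpms[[1]]$maps[[1]]
  for (s in subject_tpms) check_grid(ref, s$maps[[1]])
  avg <- lapply(classes, function(cl)
    Reduce(`+`, lapply(subject_tpms, function(s) s$maps[[cl]]$data)) /
      length(subject_tpms))
  if (smooth_fwhm_mm > 0) {
    vs <- voxel_size(ref)
    avg <- lapply(avg, function(a) smooth_array(a, smooth_fwhm_mm / (2.355 * vs)))
  }
  tot <- Reduce(`+`, avg)
  brain <- tot > 0.05
  maps <- lapply(avg, function(a) {
    a <- ifelse(brain, a + eps, 0)
    a
  })
  tot2 <- Reduce(`+`, maps)
  maps <- lapply(maps, function(a) ifelse(brain, a / pmax(tot2, eps), 0))
  tpm_set(stats::setNames(lapply(maps, function(a) vol_like(ref, a)), classes))
}

#' Grow a lacune mask from a seed point by intensity-bounded region growing
#'
#' 6-connected space-filling from the seed: one dilation layer is accepted
#' per iteration, restricted to voxels whose intensity lies in
#' \[`lower`, `upper`\], until closure or `max_iters` iterations (the
#' field-standard settings are thresholds 350-500 with 500 iterations on
#' scanner-unit T1 images; intensity bounds are in the units of `t1`).
#'
#' @param t1 intensity [volume]
#' @param seed_point length-3 voxel index (1-based)
#' @param lower,upper intensity bounds
#' @param max_iters maximum dilation layers (default 500)
#' @return binary mask [volume]
#' @export
grow_lacune <- function(t1, seed_point, lower, upper, max_iters = 500L) {
  d <- dim(t1$data)
  sp <- as.integer(seed_point)
  stop_if(length(sp) != 3 || any(sp < 1) || any(sp > d),
          "seed point outside the volume")
  val <- t1$data[sp[1], sp[2], sp[3]]
  stop_if(val < lower || val > upper,
          "seed intensity outside [lower, upper]")
  inrange <- (t1$data >= lower & t1$data <= upper) * 1L
  seed_lin0 <- (sp[1] - 1) + d[1] * (sp[2] - 1) + d[1] * d[2] * (sp[3] - 1)
  m <- cpp_region_grow(as.integer(inrange), d, seed_lin0, as.integer(max_iters))
  vol_like(t1, array(as.numeric(m), d))
}

#' Skull-strip a volume using tissue probability maps
#'
#' The brain mask is the set of voxels whose total tissue probability
#' (GM + WM + CSF) reaches `threshold`, reduced to its largest 6-connected
#' component; the input volume is zeroed outside it.
#'
#' @param vol [volume] to strip
#' @param tpms_or_segs [tpm_set] with maps named `gm`, `wm`, `csf` (other
#'   classes are ignored)
#' @param threshold probability threshold in (0, 1), default 0.1
#' @return list with `volume` (stripped) and `mask`
#' @export
skull_strip <- function(vol, tpms_or_segs, threshold = 0.1) {
  stop_if(threshold <= 0 || threshold >= 1, "threshold must lie in (0, 1)")
  stopifnot(inherits(tpms_or_segs, "tpm_set"))
  check_grid(vol, tpms_or_segs$maps[[1]])
  use <- intersect(c("gm", "wm", "csf"), names(tpms_or_segs$maps))
  if (length(use) == 0) use <- names(tpms_or_segs$maps)
  tot <- Reduce(`+`, lapply(tpms_or_segs$maps[use], function(m) m$data))
  mask <- tot >= threshold
  stop_if(!any(mask), "empty brain mask at this threshold")
  d <- dim(vol$data)
  labs <- cpp_label_components(as.integer(mask), d)
  ncomp <- attr(labs, "n_components")
  if (ncomp > 1) {
    counts <- tabulate(labs, nbins = ncomp)
    mask <- array(labs == which.max(counts), d)
  }
  stripped <- vol_like(vol, vol$data * mask)
  list(volume = stripped, mask = vol_like(vol, mask * 1))
}
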