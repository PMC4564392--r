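test_that("EM recovers well-separated single-channel mixtures", {
  set.seed(7)
  d <- c(28, 28, 26)
  n <- prod(d)
  x <- c(rnorm(floor(n / 2), 30, 5), rnorm(ceiling(n / 2), 90, 5))
  v <- volume(array(x, d))
  mask <- volume(array(1, d))
  m <- fit_mixture(list(v), mask, K = 2, seed = 1)
  mu <- sort(m$means[, 1])
  expect_lt(abs(mu[1] - 30), 1)
  expect_lt(abs(mu[2] - 90), 1)
  expect_lt(max(abs(sort(m$weights) - 0.5)), 0.02)
  # monotone log-likelihood, asserted every iteration
  expect_true(all(diff(m$loglik) > -1e-6 * abs(m$loglik[-1])))
})

test_that("two-channel EM recovers phantom class means and weights", {
  s <- small_lesioned_subject(seed = 3, n_wmh = 40)
  brain <- vol_like_t(s$labels, dilate6((s$labels$data > 0) * 1, 2))
  fit <- fit_mixture(list(t1 = s$t1, flair = s$flair), brain, K = 4, seed = 2)
  truth <- rbind(c(25, 20), c(60, 60), c(90, 50), c(70, 95))
  sep <- min(dist(truth))
  # match classes to truth by nearest mean
  for (k in 1:4) {
    errs <- sqrt(rowSums(sweep(fit$means, 2, truth[k, ])^2))
    expect_lt(min(errs), 0.02 * sep)
  }
  # realised class fractions within the mask
  lab <- s$labels$data
  inb <- brain$data > 0
  les <- (s$wmh$data > 0 | s$li$data > 0) & s$li_core$data == 0
  frac <- c(sum(inb & lab == 0 & !les) + sum(s$li_core$data > 0 & inb),
            sum(inb & lab == 1 & !les),
            sum(inb & lab == 2 & !les), sum(les & inb)) / sum(inb)
  for (k in 1:4) {
    errs <- sqrt(rowSums(sweep(fit$means, 2, truth[k, ])^2))
    expect_lt(abs(fit$weights[which.min(errs)] - frac[k]), 0.03)
  }
})

test_that("one-hot priors dominate the posterior argmax", {
  s <- small_lesioned_subject(seed = 5, n_wmh = 3, n_li = 0)
  tp <- truth_tpms(s$labels)
  mask <- volume(array(1, dim(s$labels$data)), affine = s$labels$affine)
  fit <- fit_mixture(list(s$t1), mask, priors = tp, seed = 1)
  post <- posterior_maps(fit, list(s$t1), priors = tp, mask = mask)
  am <- pmax(post$maps$gm$data, pmax(post$maps$wm$data, post$maps$csf$data))
  lab_am <- (post$maps$gm$data == am) * 1 + (post$maps$wm$data == am) * 2 +
    (post$maps$csf$data == am) * 0
  # with one-hot priors the prior term forces the truth label everywhere
  # except at extreme intensity outliers that overcome the prior floor
  match <- mean((lab_am == 1) == (s$labels$data == 1))
  expect_gte(match, 1 - 1e-4)
  # posteriors sum to 1 in-mask
  tot <- post$maps$gm$data + post$maps$wm$data + post$maps$csf$data
  expect_lt(max(abs(tot - 1)), 1e-6)
})

test_that("raising a class prior never lowers its posterior", {
  s <- small_lesioned_subject(seed = 8, n_wmh = 3, n_li = 0)
  mask <- volume(array(1, dim(s$labels$data)), affine = s$labels$affine)
  flat <- lapply(1:3, function(i)
    volume(array(1 / 3, dim(s$labels$data)), affine = s$labels$affine))
  pr1 <- tpm_set(stats::setNames(flat, c("gm", "wm", "csf")))
  fit <- fit_mixture(list(s$t1), mask, priors = pr1, seed = 1)
  p1 <- posterior_maps(fit, list(s$t1), priors = pr1, mask = mask)
  boosted <- list(volume(array(0.6, dim(s$labels$data)), affine = s$labels$affine),
                  volume(array(0.2, dim(s$labels$data)), affine = s$labels$affine),
                  volume(array(0.2, dim(s$labels$data)), affine = s$labels$affine))
  pr2 <- tpm_set(stats::setNames(boosted, c("gm", "wm", "csf")))
  p2 <- posterior_maps(fit, list(s$t1), priors = pr2, mask = mask)
  expect_true(all(p2$maps$gm$data >= p1$maps$gm$data - 1e-9))
})

test_that("lesion-aware two-channel segmentation fixes the T1-only failure", {
  s <- small_lesioned_subject(seed = 13, n_wmh = 25)
  mask <- volume(array(1, dim(s$labels$data)), affine = s$labels$affine)
  tp <- truth_tpms(s$labels)
  wmh_prior <- vol_like_t(s$labels, 0.25 * tp$maps$wm$data)
  priors4 <- tpm_set(list(gm = tp$maps$gm,
                          wm = vol_like_t(s$labels, 0.75 * tp$maps$wm$data),
                          csf = tp$maps$csf, wmh = wmh_prior))
  fit2 <- fit_mixture(list(t1 = s$t1, flair = s$flair), mask,
                      priors = priors4, seed = 1)
  post2 <- posterior_maps(fit2, list(t1 = s$t1, flair = s$flair),
                          priors = priors4, mask = mask)
  inside <- s$wmh$data > 0
  frac2 <- mean(post2$maps$wmh$data[inside] > post2$maps$gm$data[inside])
  expect_gte(frac2, 0.9)

  # naive prior-free T1-only segmentation of the skull-stripped image
  # reproduces the failure mode: lesion voxels land in GM, not WM
  brain <- vol_like_t(s$labels, dilate6((s$labels$data > 0) * 1, 2))
  fit1 <- fit_mixture(list(t1 = s$t1), brain, K = 3, seed = 1)
  post1 <- posterior_maps(fit1, list(t1 = s$t1), mask = brain)
  names(post1$maps) <- c("csf", "gm", "wm")[order(order(fit1$means[, 1]))]
  frac1 <- mean(post1$maps$gm$data[inside] > post1$maps$wm$data[inside])
  expect_gt(frac1, 0.5)

  # Dice(GM) against truth with population priors and low noise
  quiet <- intensity_model(covs = rep(list(diag(c(1, 1))), 5))
  img <- render_intensities(s$labels, s$wmh, s$li, quiet,
                            li_core = s$li_core, seed = 2)
  fitq <- fit_mixture(list(img$t1), mask, priors = tp, seed = 1)
  postq <- posterior_maps(fitq, list(img$t1), priors = tp, mask = mask)
  gm_hat <- postq$maps$gm$data >= 0.5
  gm_true <- s$labels$data == 1
  dice <- 2 * sum(gm_hat & gm_true) / (sum(gm_hat) + sum(gm_true))
  expect_gte(dice, 0.95)
})

test_that("degenerate fits are rejected", {
  v <- volume(array(5, c(6, 6, 6)))
  mask <- volume(array(1, c(6, 6, 6)))
  expect_error(fit_mixture(list(v), mask, K = 3, seed = 1), "degenerate")
  empty <- volume(array(0, c(6, 6, 6)))
  expect_error(fit_mixture(list(v), empty, K = 2, seed = 1), "empty mask")
})

test_that("population TPMs average, floor and renormalise", {
  d <- c(10, 10, 10)
  one <- function(g, w, c0) tpm_set(list(
    gm = volume(array(g, d)), wm = volume(array(w, d)),
    csf = volume(array(c0, d))))
  a <- one(1, 0, 0); b <- one(0, 1, 0)
  pop <- build_population_tpms(list(a, b), smooth_fwhm_mm = 0)
  expect_equal(pop$maps$gm$data[5, 5, 5], 0.5, tolerance = 2e-3)
  tot <- Reduce(`+`, lapply(pop$maps, function(m) m$data))
  expect_lt(max(tot), 1 + 1e-4)
  expect_true(all(sapply(pop$maps, function(m) min(m$data)) > 0))  # floor
  same <- build_population_tpms(list(a, a), smooth_fwhm_mm = 0)
  expect_equal(same$maps$gm$data[2, 2, 2], 1, tolerance = 3e-3)
})

test_that("lacune region growing matches a connected-component oracle", {
  d <- c(24, 24, 24)
  t1 <- volume(array(0, d))
  centre <- c(12, 12, 12)
  ig <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  r <- sqrt((ig$x - 12)^2 + (ig$y - 12)^2 + (ig$z - 12)^2)
  t1$data[r <= 5] <- 425
  m <- grow_lacune(t1, centre, 350, 500)
  expect_identical(m$data > 0, t1$data >= 350 & t1$data <= 500)

  one_layer <- grow_lacune(t1, centre, 350, 500, max_iters = 1)
  expect_lte(sum(one_layer$data), 7)

  expect_error(grow_lacune(t1, c(1, 1, 1), 350, 500), "outside")
})

test_that("skull strip keeps the largest component above threshold", {
  d <- c(20, 20, 20)
  gm <- volume(array(0, d)); wm <- volume(array(0, d)); csf <- volume(array(0, d))
  gm$data[5:15, 5:15, 5:15] <- 0.8
  csf$data[5:15, 5:15, 5:15] <- 0.2
  # disconnected speck with probability 0.2
  csf$data[2, 2, 2] <- 0.2
  tp <- tpm_set(list(gm = gm, wm = wm, csf = csf))
  vol <- volume(array(100, d))
  ss <- skull_strip(vol, tp, threshold = 0.1)
  expect_equal(ss$mask$data[2, 2, 2], 0)       # speck removed
  expect_true(all(ss$mask$data[6:14, 6:14, 6:14] == 1))
  expect_true(all(ss$volume$data[ss$mask$data == 0] == 0))
  expect_error(skull_strip(vol, tp, threshold = 1.0), "\\(0, 1\\)")
})
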