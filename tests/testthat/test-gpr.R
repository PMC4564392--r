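# toy feature maps: n subjects with a dominant spatial pattern plus noise
toy_kernel <- function(n = 20, d = c(6, 5, 4), score = NULL, noise = 0.5,
                       seed = 2) {
  with_seed_t(seed, {
    D <- prod(d)
    s <- score %||% rnorm(n)
    pat <- rnorm(D)
    F <- outer(s, pat) + noise * matrix(rnorm(n * D), n)
    mask <- volume(array(1, d))
    maps <- lapply(seq_len(n), function(i)
      volume(array(F[i, ], d)))
    list(kernel = build_linear_kernel(maps, mask), F = F, s = s, maps = maps,
         mask = mask)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("linear kernel equals brute-force dot products and is PSD", {
  tk <- toy_kernel(n = 8, d = c(5, 2, 1))        # 10-voxel toy
  Fc <- sweep(tk$F, 2, colMeans(tk$F))
  K_brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) K_brute[i, j] <- sum(Fc[i, ] * Fc[j, ]) / ncol(Fc)
  expect_lt(max(abs(tk$kernel$K - K_brute)), 1e-10)
  ev <- eigen(tk$kernel$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * sum(diag(tk$kernel$K)))

  # duplicated subjects give identical kernel rows
  maps <- c(tk$maps, tk$maps[1])
  km <- build_linear_kernel(maps, tk$mask)
  expect_lt(max(abs(km$K[1, ] - km$K[9, ])), 1e-10)
})

test_that("confound residualisation: closed form, idempotence, annihilation", {
  tk <- toy_kernel(n = 12)
  K <- tk$kernel$K
  # intercept only = double centring
  Kc <- residualise_confounds(K)
  n <- nrow(K)
  J <- diag(n) - matrix(1 / n, n, n)
  expect_lt(max(abs(Kc - J %*% K %*% J)), 1e-10)
  # idempotence
  conf <- cbind(with_seed_t(4, rnorm(12)))
  k1 <- residualise_confounds(tk$kernel, conf)
  k2 <- residualise_confounds(k1, conf)
  expect_lt(max(abs(k1$K - k2$K)), 1e-8)
  # features exactly linear in the confounds are annihilated
  conf2 <- with_seed_t(5, cbind(rnorm(12)))
  Flin <- outer(conf2[, 1], with_seed_t(6, rnorm(40)))
  maps <- lapply(seq_len(12), function(i) volume(array(Flin[i, ], c(5, 4, 2))))
  kml <- build_linear_kernel(maps, volume(array(1, c(5, 4, 2))))
  klr <- residualise_confounds(kml, conf2)
  expect_lt(norm(klr$K, "F") / norm(kml$K, "F"), 1e-6)
})

test_that("GP fit finds signal and noise regimes and improves on its init", {
  tk <- toy_kernel(n = 24, noise = 0.2)
  K <- tk$kernel$K
  # target = top eigenvector: nearly noiseless fit, training r > 0.99
  eg <- eigen(K, symmetric = TRUE)
  y <- eg$vectors[, 1] + 1e-3 * with_seed_t(3, rnorm(24))
  m <- gpr_fit(K, y)
  expect_lt(m$theta_n / m$theta_s, 0.05)
  expect_gt(cor(predict(m), y), 0.99)
  # pure-noise target: signal-to-noise ratio small
  y0 <- with_seed_t(8, rnorm(24))
  m0 <- gpr_fit(K, y0)
  expect_lt(m0$theta_s * mean(diag(K)) / m0$theta_n, 0.1)
  # optimised marginal likelihood beats an arbitrary initial guess
  lml_at <- function(ths, thn) {
    S <- ths * K + thn * diag(24)
    -0.5 * as.numeric(t(y - mean(y)) %*% solve(S, y - mean(y))) -
      0.5 * determinant(S)$modulus - 12 * log(2 * pi)
  }
  expect_gte(m$lml + 1e-6, lml_at(1, 1))
  expect_error(gpr_fit(K, rep(1, 23)), "length")
})

test_that("leave-one-out prediction detects signal and is order-invariant", {
  tk <- toy_kernel(n = 40, noise = 0.3, seed = 5)
  y <- tk$s + 0.02 * with_seed_t(6, rnorm(40))
  rep <- loo_cv(tk$kernel, y)
  expect_gt(rep$pearson_r, 0.95)
  expect_equal(rep$r_squared, rep$pearson_r^2)
  expect_equal(rep$rmse, sqrt(mean((rep$predictions - y)^2)))

  # permutation equivariance of the predictions
  pm <- with_seed_t(7, sample(40))
  K2 <- tk$kernel$K[pm, pm]
  rep2 <- loo_cv(K2, y[pm])
  expect_lt(max(abs(rep2$predictions - rep$predictions[pm])), 1e-8)

  # constant target is flagged
  repc <- loo_cv(tk$kernel$K, rep(5, 40))
  expect_true(repc$constant_target)
  expect_equal(repc$pearson_r, 0)
})

test_that("confound correction removes confound-routed predictability", {
  n <- 30
  age <- with_seed_t(11, rnorm(n, 70, 8))
  pat <- with_seed_t(12, rnorm(200))
  F <- outer(age, pat) + 0.5 * with_seed_t(13, matrix(rnorm(n * 200), n))
  maps <- lapply(seq_len(n), function(i) volume(array(F[i, ], c(10, 10, 2))))
  km <- build_linear_kernel(maps, volume(array(1, c(10, 10, 2))))
  y <- 100 * age + with_seed_t(14, rnorm(n, 0, 50))
  r_raw <- loo_cv(km, y)$pearson_r
  r_cor <- loo_cv(km, y, confounds = cbind(age))$pearson_r
  expect_gt(r_raw, 0.9)
  # with the only association routed through age, corrected r falls below
  # the positive permutation envelope
  perm <- permutation_significance(km, y, confounds = cbind(age),
                                   n_perm = 199, seed = 3)
  expect_lt(r_cor, quantile(perm$r_perm, 0.95))
  expect_gt(perm$p, 0.05)
})

test_that("permutation significance is seeded, bounded and detects signal", {
  tk <- toy_kernel(n = 24, noise = 0.3, seed = 9)
  y <- tk$s + 0.05 * with_seed_t(10, rnorm(24))
  p1 <- permutation_significance(tk$kernel, y, n_perm = 199, seed = 4)
  p2 <- permutation_significance(tk$kernel, y, n_perm = 199, seed = 4)
  expect_identical(p1$r_perm, p2$r_perm)
  expect_gte(p1$p, 1 / 200)
  expect_lt(p1$p, 0.05)
})

test_that("weight map satisfies the dual-primal identity and scales with y", {
  tk <- toy_kernel(n = 16, noise = 0.4, seed = 21)
  y <- tk$s + 0.1 * with_seed_t(22, rnorm(16))
  m <- gpr_fit(tk$kernel, y)
  w <- weight_map(m, tk$kernel)
  wv <- w$data[tk$kernel$mask_idx]
  pred_primal <- m$theta_s * as.numeric(tk$kernel$features %*% wv) + m$offset
  expect_lt(max(abs(pred_primal - predict(m))), 1e-6)
  # scaling the targets scales the effective primal predictor theta_s * w
  # (the variance hyperparameters absorb the square of the scale)
  m2 <- gpr_fit(tk$kernel, 3 * y)
  w2 <- weight_map(m2, tk$kernel)
  expect_lt(max(abs(m2$theta_s * w2$data - 3 * m$theta_s * w$data)) /
              max(abs(m$theta_s * w$data)), 1e-4)
  # all-zero alpha gives a zero map
  mz <- m; mz$alpha <- rep(0, 16)
  expect_true(all(weight_map(mz, tk$kernel)$data == 0))
})
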