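ref32 <- function() make_labelmap(phantom_spec(grid_shape = 32, voxel_size_mm = 2,
                                               wm_radius_mm = 18,
                                               gm_thickness_mm = 5))

test_that("exponential map: identity, translation and inverse consistency", {
  lab <- ref32()
  d <- dim(lab$data)
  v0 <- velocity_field(lapply(1:3, function(j) array(0, d)), lab)
  phi0 <- exp_velocity(v0)
  expect_equal(max(abs(unlist(phi0$disp))), 0)
  expect_true(all(jacobian_det(phi0)$data == 1))

  # uniform translation: exact shift and unit Jacobian away from the
  # field-of-view boundary (displacements are zero outside the grid)
  vt <- velocity_field(list(array(3, d), array(0, d), array(0, d)), lab)
  phit <- exp_velocity(vt)
  core <- 11:(d[1] - 10)     # B-spline boundary influence decays ~0.27^d
  expect_lt(max(abs(phit$disp[[1]][core, core, core] - 1.5)), 1e-6)
  expect_lt(max(abs(phit$disp[[2]][core, core, core])), 1e-6)
  jt <- jacobian_det(phit)$data
  expect_lt(max(abs(jt[core, core, core] - 1)), 1e-5)

  # random smooth field: forward o inverse within 0.1 voxel
  v <- random_velocity(lab, amplitude_mm = 1.5, seed = 9)
  phi <- exp_velocity(v)
  phinv <- exp_velocity(negate(v))
  comp <- compose_deformations(phi, phinv)
  err <- sqrt(comp$disp[[1]]^2 + comp$disp[[2]]^2 + comp$disp[[3]]^2)
  expect_lt(max(err), 0.1)
  # produced deformations are diffeomorphic
  expect_gt(min(jacobian_det(phi)$data), 0)
  expect_error(velocity_field(list(array(NaN, d), array(0, d), array(0, d)),
                              lab), "finite")
})

test_that("warping: identity, integer shifts, and smooth round trips", {
  lab <- ref32()
  d <- dim(lab$data)
  blob <- gaussian_smooth(vol_like_t(lab, (lab$data > 0) * 1), 6)
  idphi <- exp_velocity(velocity_field(lapply(1:3, function(j) array(0, d)), lab))
  expect_identical(warp_volume(blob, idphi, order = 1)$data, blob$data)

  shift2 <- exp_velocity(velocity_field(list(array(4, d), array(0, d),
                                             array(0, d)), lab))   # 2 voxels
  w <- warp_volume(blob, shift2, order = 0)
  core <- 5:(d[1] - 5)
  expect_same_array(w$data[core, core, core], blob$data[core + 2, core, core])

  v <- random_velocity(lab, amplitude_mm = 2, seed = 5)
  phi <- exp_velocity(v); phinv <- exp_velocity(negate(v))
  back <- warp_volume(warp_volume(blob, phi), phinv)
  expect_gt(cor(as.numeric(back$data), as.numeric(blob$data)), 0.99)

  mk <- warp_mask(vol_like_t(lab, (lab$data == 2) * 1), phi)
  expect_true(all(mk$data %in% c(0, 1)))
})

test_that("Jacobian of a uniform scaling is s^3", {
  lab <- ref32()
  d <- dim(lab$data)
  s <- 1.04
  ctr <- (d - 1) / 2
  ig <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  disp <- list(array((s - 1) * (ig$x - ctr[1]), d),
               array((s - 1) * (ig$y - ctr[2]), d),
               array((s - 1) * (ig$z - ctr[3]), d))
  phi <- lesionmorph:::deformation_field(disp, lab$affine, d)
  jd <- jacobian_det(phi)$data
  expect_lt(max(abs(jd - s^3)), 1e-6)
})

test_that("pair registration recovers a known warp and rejects mismatches", {
  lab <- ref32()
  mk <- function(cls) gaussian_smooth(vol_like_t(lab, (lab$data == cls) * 1), 4)
  fixed <- tpm_set(list(gm = mk(1), wm = mk(2), csf = mk(0)))
  v <- register_pair(fixed, fixed)
  phi <- exp_velocity(v)
  expect_lt(max(sqrt(phi$disp[[1]]^2 + phi$disp[[2]]^2 + phi$disp[[3]]^2)), 0.2)

  vknown <- random_velocity(lab, amplitude_mm = 3, seed = 4)
  phik <- exp_velocity(vknown)
  moving <- tpm_set(lapply(fixed$maps, function(m) warp_volume(m, phik)))
  ssd0 <- sum(mapply(function(a, b) sum((a$data - b$data)^2),
                     moving$maps, fixed$maps))
  vrec <- register_pair(moving, fixed)
  phir <- exp_velocity(vrec)
  rec <- lapply(moving$maps, function(m) warp_volume(m, phir))
  ssd1 <- sum(mapply(function(a, b) sum((a$data - b$data)^2), rec, fixed$maps))
  expect_lt(ssd1 / ssd0, 0.2)                      # >= 80% SSD reduction
  tr <- attr(vrec, "ssd_trace")
  for (sc in tr) expect_true(all(diff(sc) <= 1e-9))
  expect_gt(min(jacobian_det(phir)$data), 0)

  wrong <- tpm_set(list(a = fixed$maps$gm, b = fixed$maps$wm, c = fixed$maps$csf))
  expect_error(register_pair(wrong, fixed), "classes")
})

test_that("template building averages, sharpens and recentres", {
  lab <- ref32()
  mk <- function(cls) gaussian_smooth(vol_like_t(lab, (lab$data == cls) * 1), 4)
  base <- tpm_set(list(gm = mk(1), wm = mk(2), csf = mk(0)))
  # identical subjects: template equals them
  bt0 <- build_template(list(base, base), n_outer = 1,
                        params = reg_params(n_scales = 2, iters_per_scale = 4))
  expect_lt(mean((bt0$template$maps$gm$data - base$maps$gm$data)^2), 1e-4)

  subj <- lapply(1:3, function(i) {
    phi <- exp_velocity(random_velocity(lab, amplitude_mm = 2, seed = i * 7))
    tpm_set(lapply(base$maps, function(m) warp_volume(m, phi)))
  })
  # n_outer 0: plain average
  plain <- build_template(subj, n_outer = 0)
  avg <- Reduce(`+`, lapply(subj, function(s) s$maps$gm$data)) / 3
  expect_same_array(plain$template$maps$gm$data, avg, tol = 1e-12)

  bt <- build_template(subj, n_outer = 2,
                       params = reg_params(n_scales = 2, iters_per_scale = 8))
  # optimisation strictly decreases the mean cross-subject SSD
  expect_lt(tail(bt$ssd_trace, 1), bt$ssd_trace[1])
  # sharper than the naive average: more high-probability GM
  expect_gt(sum(bt$template$maps$gm$data > 0.7), sum(avg > 0.7))
  expect_lte(max(bt$template$maps$gm$data), 1 + 1e-6)
})

test_that("modulation preserves volume and behaves linearly", {
  lab <- ref32()
  gm <- gaussian_smooth(vol_like_t(lab, (lab$data == 1) * 1), 4)
  v <- random_velocity(lab, amplitude_mm = 2.5, seed = 12)
  phi <- exp_velocity(v)
  wgm <- warp_volume(gm, phi)
  jac <- jacobian_det(phi)
  mod <- modulate(wgm, jac)
  expect_lt(abs(sum(mod$data) - sum(gm$data)) / sum(gm$data), 0.02)
  expect_identical(modulate(wgm, vol_like_t(wgm, array(1, dim(wgm$data))))$data,
                   wgm$data)
  expect_same_array(modulate(wgm, vol_like_t(jac, 2 * jac$data))$data,
                    2 * mod$data, tol = 1e-12)
})

test_that("warped-weighted smoothing averages thickness without bleeding", {
  lab <- make_labelmap(phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = 1,
                                    wm_radius_mm = 8, gm_thickness_mm = 4,
                                    geometry = "flat_slab"))
  gm <- (lab$data == 1) * 1
  w <- vol_like_t(lab, gm)
  # constant thickness with any positive weight stays constant in-support
  tconst <- vol_like_t(lab, gm * 2.5)
  out <- warped_weighted_smooth(tconst, w, fwhm_mm = 6)
  expect_lt(max(abs(out$data[gm > 0] - 2.5)), 1e-6)
  # convexity: output within the input range
  tstep <- vol_like_t(lab, gm * rep(c(3, 5), each = 12 * 24 * 24 / 2))
  out2 <- warped_weighted_smooth(tstep, w, fwhm_mm = 6)
  expect_gte(min(out2$data[gm > 0]), 3 - 1e-9)
  expect_lte(max(out2$data[gm > 0]), 5 + 1e-9)
  # slab phantom: in-mask mean within 5% of true thickness
  thick <- vbct(slab_tpms(4), vbct_params())
  wws <- warped_weighted_smooth(thick, vol_like_t(thick, (thick$data > 0) * 1),
                                fwhm_mm = 6)
  expect_lt(abs(mean(wws$data[thick$data > 0]) - 4) / 4, 0.05)
  expect_error(warped_weighted_smooth(tconst, vol_like_t(lab, array(0, dim(lab$data)))),
               "all-zero")
})

test_that("deformation fields round-trip through 4-D NIfTI", {
  lab <- ref32()
  v <- random_velocity(lab, amplitude_mm = 2, seed = 3)
  phi <- exp_velocity(v)
  f <- tempfile(fileext = ".nii.gz")
  write_deformation(phi, f)
  phi2 <- read_deformation(f)
  for (j in 1:3)
    expect_lt(max(abs(phi2$disp[[j]] - phi$disp[[j]])), 1e-3)  # float32
  expect_same_array(phi2$affine, phi$affine)
  unlink(f)
})
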