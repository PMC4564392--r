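make_probs <- function(d, gm, wm, csf) {
  list(gm = volume(array(gm, d)), wm = volume(array(wm, d)),
       csf = volume(array(csf, d)))
}

test_that("WMH repair moves GM mass to WM only inside the mask", {
  d <- c(8, 8, 8)
  p <- make_probs(d, 0.7, 0.2, 0.1)
  mask <- volume(array(0, d)); mask$data[2:4, 2:4, 2:4] <- 1
  r <- repair_wmh(p$gm, p$wm, mask)
  expect_equal(r$gm$data[3, 3, 3], 0)
  expect_equal(r$wm$data[3, 3, 3], 0.9)
  # outside untouched, bitwise
  expect_identical(r$gm$data[mask$data == 0], p$gm$data[mask$data == 0])
  expect_identical(r$wm$data[mask$data == 0], p$wm$data[mask$data == 0])
  # conservation
  expect_equal(sum(r$gm$data + r$wm$data), sum(p$gm$data + p$wm$data))
  # empty mask is the identity
  r0 <- repair_wmh(p$gm, p$wm, volume(array(0, d)))
  expect_identical(r0$gm$data, p$gm$data)
})

test_that("LI consensus takes the per-voxel majority with WM precedence", {
  d <- c(6, 6, 6)
  subj <- function(gm, wm, csf) tpm_set(make_probs(d, gm, wm, csf))
  m <- volume(array(1, d))
  # 2 WM-dominant vs 1 GM-dominant -> WM
  lab <- consensus_li_classes(list(m, m, m),
                              list(subj(.1, .8, .1), subj(.2, .7, .1),
                                   subj(.8, .1, .1)))
  expect_true(all(lab$data == 2))
  # unanimity
  lab2 <- consensus_li_classes(list(m, m, m),
                               list(subj(.1, .8, .1), subj(.1, .8, .1),
                                    subj(.1, .8, .1)))
  expect_true(all(lab2$data == 2))
  # tie WM/GM -> WM by precedence
  lab3 <- consensus_li_classes(list(m, m),
                               list(subj(.8, .1, .1), subj(.1, .8, .1)))
  expect_true(all(lab3$data == 2))
  # uncovered voxels are 0
  m0 <- volume(array(0, d)); m0$data[1, 1, 1] <- 1
  lab4 <- consensus_li_classes(list(m0), list(subj(.1, .8, .1)))
  expect_equal(lab4$data[1, 1, 1], 2)
  expect_equal(sum(lab4$data), 2)
  expect_error(consensus_li_classes(list(), list()), "empty")
})

test_that("LI repair assigns full mass to the consensus class", {
  d <- c(6, 6, 6)
  p <- make_probs(d, 0.1, 0.2, 0.7)
  mask <- volume(array(0, d)); mask$data[3, 3, 3] <- 1
  cons <- volume(array(2, d))    # WM everywhere
  r <- repair_li(p$gm, p$wm, p$csf, mask, cons)
  expect_equal(r$maps$gm$data[3, 3, 3], 0)
  expect_equal(r$maps$wm$data[3, 3, 3], 1.0)
  expect_equal(r$maps$csf$data[3, 3, 3], 0)
  out <- mask$data == 0
  expect_identical(r$maps$csf$data[out], p$csf$data[out])
  tot_in <- sum(sapply(r$maps, function(m) sum(m$data)))
  tot_pre <- sum(p$gm$data + p$wm$data + p$csf$data)
  expect_equal(tot_in, tot_pre)

  # consensus 0 falls back to the subject's own argmax (here CSF)
  cons0 <- volume(array(0, d))
  r2 <- repair_li(p$gm, p$wm, p$csf, mask, cons0)
  expect_equal(r2$maps$csf$data[3, 3, 3], 1.0)
  expect_equal(attr(r2, "n_fallback"), 1L)

  # empty mask is the identity
  r3 <- repair_li(p$gm, p$wm, p$csf, volume(array(0, d)), cons)
  expect_identical(r3$maps$gm$data, p$gm$data)
})

test_that("brain masking shifts removed GM/WM mass into CSF", {
  d <- c(6, 6, 6)
  tp <- tpm_set(make_probs(d, 0.3, 0.3, 0.2))
  brain <- volume(array(0, d)); brain$data[2:5, 2:5, 2:5] <- 1
  r <- apply_brain_mask(tp, brain)
  expect_equal(r$maps$gm$data[1, 1, 1], 0)
  expect_equal(r$maps$csf$data[1, 1, 1], 0.8)
  expect_equal(r$maps$gm$data[3, 3, 3], 0.3)
  tot0 <- tp$maps$gm$data + tp$maps$wm$data + tp$maps$csf$data
  tot1 <- r$maps$gm$data + r$maps$wm$data + r$maps$csf$data
  expect_same_array(tot0, tot1, tol = 1e-12)
  all_in <- apply_brain_mask(tp, volume(array(1, d)))
  expect_identical(all_in$maps$gm$data, tp$maps$gm$data)
})

test_that("volume report counts masks and thresholds TIV inclusively", {
  d <- c(10, 10, 10)
  tp <- tpm_set(make_probs(d, 0.05, 0.05, 0.09))     # sum 0.19 < 0.2
  wmh <- volume(array(0, d)); wmh$data[1:4, 1:5, 1:5] <- 1  # 100 voxels
  li <- volume(array(0, d))
  vr <- compute_volumes(tp, wmh, li)
  expect_equal(vr$wmhv_mm3, 100)
  expect_equal(vr$tiv_mm3, 0)
  tp2 <- tpm_set(make_probs(d, 0.05, 0.05, 0.10))    # sum exactly 0.2
  expect_equal(compute_volumes(tp2, wmh, li)$tiv_mm3, 1000)
  expect_equal(vr$class_volumes_mm3[["gm"]], 0.05 * 1000)
})

test_that("repair leaves phantom WMH voxels argmax-WM and is conservative", {
  s <- small_lesioned_subject(seed = 21, n_wmh = 10, n_li = 2)
  # corrupted maps: WMH as GM, gliosis as CSF (the naive failure mode)
  lab <- s$labels$data
  wmh_like <- s$wmh$data > 0 | (s$li$data > 0 & s$li_core$data == 0)
  gm <- vol_like_t(s$labels, ((lab == 1 & s$li_core$data == 0) | wmh_like) * 1)
  wm <- vol_like_t(s$labels, (lab == 2 & !wmh_like & s$li_core$data == 0) * 1)
  csf <- vol_like_t(s$labels, ((lab == 0 & !wmh_like) | s$li_core$data > 0) * 1)
  pre_mass <- gm$data + wm$data + csf$data

  r1 <- repair_wmh(gm, wm, s$wmh)
  cons <- consensus_li_classes(list(s$li), list(tpm_set(list(gm = r1$gm,
                                                             wm = r1$wm,
                                                             csf = csf))))
  r2 <- repair_li(r1$gm, r1$wm, csf, s$li, cons)
  inside <- s$wmh$data > 0
  argmax_wm <- r2$maps$wm$data[inside] >= r2$maps$gm$data[inside] &
    r2$maps$wm$data[inside] >= r2$maps$csf$data[inside]
  expect_true(all(argmax_wm))
  post_mass <- Reduce(`+`, lapply(r2$maps, function(m) m$data))
  expect_lt(max(abs(post_mass - pre_mass)), 1e-6)
  outside <- s$wmh$data == 0 & s$li$data == 0
  expect_identical(r2$maps$gm$data[outside], gm$data[outside])
})

test_that("reliability metrics behave on identical, shifted and tiny inputs", {
  a <- c(1000, 2000, 3000, 4000)
  ident <- reliability_metrics(a, a)
  expect_equal(ident$mean_variability_pct, 0)
  expect_equal(ident$icc, 1)
  expect_equal(ident$sem_mm3, 0)

  shifted <- reliability_metrics(a, a + 500)
  expect_gt(shifted$mean_variability_pct, 0)
  expect_lt(shifted$icc, 1)
  # direct formula for the variability
  expect_equal(shifted$mean_variability_pct,
               mean(abs(-500) / ((a + a + 500) / 2) * 100))

  expect_error(reliability_metrics(1000, 1100), "two pairs")
  expect_message(reliability_metrics(c(0, 1000, 2000), c(0, 1100, 1900)),
                 "zero-volume")

  # SEM from a repeats matrix
  reps <- cbind(a, a + c(10, -10, 10, -10), a)
  rr <- reliability_metrics(a, a + 20, repeats_a = reps)
  expect_equal(rr$sem_mm3, sqrt(mean(apply(reps, 1, var))))
})
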