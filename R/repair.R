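#' Reassign WMH-corrupted grey-matter probability to white matter
#'
#' Inside the binary WMH mask, all grey-matter probability is transferred
#' to white matter (`wm' = wm + gm`, `gm' = 0`); voxels outside the mask
#' are untouched, so total GM+WM mass is conserved exactly.
#'
#' @param gm,wm probability [volume]s
#' @param wmh_mask binary WMH mask [volume]
#' @return list of repaired volumes `gm` and `wm`
#' @export
repair_wmh <- function(gm, wm, wmh_mask) {
  check_grid(gm, wm, wmh_mask)
  inside <- wmh_mask$data > 0
  gm2 <- gm$data; wm2 <- wm$data
  wm2[inside] <- wm2[inside] + gm2[inside]
  gm2[inside] <- 0
  list(gm = vol_like(gm, gm2), wm = vol_like(wm, wm2))
}

#' Population-consensus tissue class under lacunar infarcts
#'
#' At every group-space voxel covered by at least one subject's LI mask,
#' the label is the tissue class that is the per-subject posterior argmax
#' most often across all subjects (computed from lesion-free tissue maps).
#' Ties break by the precedence WM > GM > CSF, since lacunar damage lives
#' in white matter.  Labels: 0 uncovered, 1 GM, 2 WM, 3 CSF.
#'
#' @param li_masks_group list of binary LI masks in group space
#' @param tpms_group list of [tpm_set]s (classes `gm`, `wm`, `csf`) in
#'   group space, one per subject
#' @return label [volume]
#' @export
consensus_li_classes <- function(li_masks_group, tpms_group) {
  stop_if(length(tpms_group) == 0, "empty subject list")
  stop_if(length(li_masks_group) != length(tpms_group),
          "mask and map lists differ in length")
  ref <- tpms_group[[1]]$maps[[1]]
  d <- dim(ref$data)
  votes <- list(gm = array(0L, d), wm = array(0L, d), csf = array(0L, d))
  covered <- array(FALSE, d)
  for (i in seq_along(tpms_group)) {
    check_grid(ref, tpms_group[[i]]$maps[[1]], li_masks_group[[i]])
    g <- tpms_group[[i]]$maps$gm$data
    w <- tpms_group[[i]]$maps$wm$data
    c0 <- tpms_group[[i]]$maps$csf$data
    am_gm <- g >= w & g >= c0
    am_wm <- w > g & w >= c0
    am_csf <- !(am_gm | am_wm)
    votes$gm <- votes$gm + am_gm
    votes$wm <- votes$wm + am_wm
    votes$csf <- votes$csf + am_csf
    covered <- covered | (li_masks_group[[i]]$data > 0)
  }
  lab <- array(0L, d)
  # precedence WM > GM > CSF on ties
  win_wm <- votes$wm >= votes$gm & votes$wm >= votes$csf
  win_gm <- !win_wm & votes$gm >= votes$csf
  lab[covered & win_wm] <- 2L
  lab[covered & win_gm & !win_wm] <- 1L
  lab[covered & !win_wm & !win_gm] <- 3L
  vol_like(ref, array(as.numeric(lab), d))
}

#' Reclassify lacunar-infarct voxels to the population-consensus class
#'
#' Within the subject's LI mask, the full tissue probability mass
#' (gm + wm + csf) at each voxel is assigned to the consensus class
#' (warped to native space beforehand).  Voxels whose consensus label is 0
#' fall back to the subject's own argmax class; their count is recorded in
#' the `n_fallback` attribute.
#'
#' @param gm,wm,csf probability [volume]s in native space
#' @param li_mask binary LI mask [volume]
#' @param consensus_native consensus label [volume] warped to the native
#'   grid (labels 0-3 as in [consensus_li_classes()])
#' @return a [tpm_set] of repaired `gm`, `wm`, `csf`
#' @export
repair_li <- function(gm, wm, csf, li_mask, consensus_native) {
  check_grid(gm, wm, csf, li_mask, consensus_native)
  g <- gm$data; w <- wm$data; c0 <- csf$data
  lab <- consensus_native$data
  inside <- li_mask$data > 0
  n_fallback <- 0L
  if (any(inside & lab == 0)) {
    fb <- inside & lab == 0
    n_fallback <- sum(fb)
    own <- ifelse(w[fb] >= g[fb] & w[fb] >= c0[fb], 2,
                  ifelse(g[fb] >= c0[fb], 1, 3))
    lab[fb] <- own
  }
  mass <- g + w + c0
  for (k in 1:3) {
    sel <- inside & lab == k
    g[sel] <- if (k == 1) mass[sel] else 0
    w[sel] <- if (k == 2) mass[sel] else 0
    c0[sel] <- if (k == 3) mass[sel] else 0
  }
  out <- tpm_set(list(gm = vol_like(gm, pmin(g, 1)),
                      wm = vol_like(wm, pmin(w, 1)),
                      csf = vol_like(csf, pmin(c0, 1))))
  attr(out, "n_fallback") <- n_fallback
  out
}

#' Apply a brain mask to tissue maps, moving removed mass to CSF
#'
#' Outside the brain mask, GM and WM are set to 0 and their probability
#' mass is added to CSF; inside, nothing changes, so the three-class sum
#' is invariant.
#'
#' @param tpms [tpm_set] with classes `gm`, `wm`, `csf`
#' @param brain binary brain mask [volume]
#' @return masked [tpm_set]
#' @export
apply_brain_mask <- function(tpms, brain) {
  check_grid(tpms$maps[[1]], brain)
  outside <- brain$data == 0
  g <- tpms$maps$gm$data; w <- tpms$maps$wm$data; c0 <- tpms$maps$csf$data
  c0[outside] <- c0[outside] + g[outside] + w[outside]
  g[outside] <- 0; w[outside] <- 0
  out <- tpms
  out$maps$gm <- vol_like(tpms$maps$gm, g)
  out$maps$wm <- vol_like(tpms$maps$wm, w)
  out$maps$csf <- vol_like(tpms$maps$csf, pmin(c0, 1))
  out
}

#' Tissue and lesion volumes from repaired segmentations
#'
#' WMHV and LIV are binary-mask voxel counts times the voxel volume; total
#' intracranial volume counts voxels whose GM+WM+CSF probability reaches
#' `tiv_threshold` (>= 0.2 by default); per-class volumes are probability
#' integrals.
#'
#' @param tpms [tpm_set] with classes `gm`, `wm`, `csf`
#' @param wmh_mask,li_mask binary lesion masks
#' @param tiv_threshold probability threshold for TIV (inclusive)
#' @return a `volume_report` list: `tiv_mm3`, `wmhv_mm3`, `liv_mm3`,
#'   `class_volumes_mm3`
#' @export
compute_volumes <- function(tpms, wmh_mask, li_mask, tiv_threshold = 0.2) {
  check_grid(tpms$maps[[1]], wmh_mask, li_mask)
  vv <- voxel_volume(tpms$maps[[1]])
  tot <- Reduce(`+`, lapply(tpms$maps[c("gm", "wm", "csf")], function(m) m$data))
  rep <- list(
    tiv_mm3 = sum(tot >= tiv_threshold) * vv,
    wmhv_mm3 = sum(wmh_mask$data > 0) * vv,
    liv_mm3 = sum(li_mask$data > 0) * vv,
    class_volumes_mm3 = vapply(tpms$maps, function(m) sum(m$data) * vv, 0)
  )
  structure(rep, class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("TIV %.0f mm^3 | WMHV %.0f mm^3 | LIV %.0f mm^3\n",
              x$tiv_mm3, x$wmhv_mm3, x$liv_mm3))
  print(round(x$class_volumes_mm3))
  invisible(x)
}

#' Reliability metrics for paired volume measurements
#'
#' Mean variability is the pairwise `|a - b| / mean(a, b) * 100`; the
#' standard error of measurement comes from the paired differences
#' (`sd(a - b) / sqrt(2)`, or from the within-subject variance of repeated
#' measurements when a repeats matrix is supplied); agreement between the
#' two measurement series is summarised by the two-way
#' absolute-agreement intraclass correlation, ICC(A,1).
#'
#' @param volumes_a,volumes_b paired measurement vectors (mm^3)
#' @param repeats_a optional matrix (subjects x repeats) of repeated
#'   measurements used for the SEM
#' @return a `reliability_report`: `sem_mm3`, `mean_variability_pct`,
#'   `sd_variability_pct`, `icc`, `n_pairs_used`
#' @export
reliability_metrics <- function(volumes_a, volumes_b, repeats_a = NULL) {
  stop_if(length(volumes_a) != length(volumes_b), "unpaired inputs")
  stop_if(length(volumes_a) < 2, "need at least two pairs")
  pm <- (volumes_a + volumes_b) / 2
  keep <- pm > 0
  if (!all(keep))
    message(sprintf("excluding %d zero-volume pair(s)", sum(!keep)))
  a <- volumes_a[keep]; b <- volumes_b[keep]
  stop_if(length(a) < 2, "fewer than two usable pairs")
  variability <- abs(a - b) / ((a + b) / 2) * 100
  sem <- if (!is.null(repeats_a)) {
    wvar <- apply(repeats_a, 1, stats::var)
    sqrt(mean(wvar))
  } else {
    stats::sd(a - b) / sqrt(2)
  }
  # two-way mixed-effects absolute agreement, single measurement
  n <- length(a); k <- 2
  Y <- cbind(a, b)
  subj_means <- rowMeans(Y); rater_means <- colMeans(Y); grand <- mean(Y)
  BMS <- k * sum((subj_means - grand)^2) / (n - 1)
  JMS <- n * sum((rater_means - grand)^2) / (k - 1)
  EMS <- (sum((Y - outer(subj_means, rep(1, k)) -
                 outer(rep(1, n), rater_means) + grand)^2)) / ((n - 1) * (k - 1))
  icc <- (BMS - EMS) / (BMS + (k - 1) * EMS + k * (JMS - EMS) / n)
  if (!is.finite(icc)) icc <- 1   # zero variance in both series
  structure(list(sem_mm3 = sem, mean_variability_pct = mean(variability),
                 sd_variability_pct = stats::sd(variability),
                 icc = max(-1, min(1, icc)), n_pairs_used = length(a)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("SEM %.1f mm^3 | variability %.2f%% (sd %.2f%%) | ICC %.3f (n = %d)\n",
              x$sem_mm3, x$mean_variability_pct, x$sd_variability_pct,
              x$icc, x$n_pairs_used))
  invisible(x)
}
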