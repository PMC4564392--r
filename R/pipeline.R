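#' Default pipeline configuration
#'
#' A single nested list mirroring every tunable of the pipeline: cohort,
#' phantom geometry, lesion and intensity models, segmentation mode,
#' repair/registration toggles, thresholds (skull-strip 0.1, TIV 0.2, WMH
#' binarisation 0.5), smoothing FWHMs (6 mm for analysis maps), VBCT
#' parameters, GLM covariates and permutation counts.  Any sub-list can be
#' overridden through `modify`.
#'
#' @param modify named list of overrides (nested lists are merged)
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(modify = list()) {
  cfg <- list(
    seed = 42L,
    cohort = list(n_subjects = 8L),
    phantom = list(),
    lesions = list(),
    intensity = list(bias_field_amplitude = 0.05),
    segmentation = "em",        # "em" (two-pass EM) or "truth" (corrupted truth maps)
    repair = TRUE,
    registration = "full",      # "full" or "none" (subjects already aligned)
    template_n_outer = 1L,
    reg = list(n_scales = 2L, iters_per_scale = 8L),
    thresholds = list(skull_strip = 0.1, tiv = 0.2, wmh = 0.5),
    smooth_fwhm_mm = 6,
    vbct = list(sampling_resolution_mm = 1),
    glm_covariates = c("wmhv_mm3", "age", "sex", "liv_mm3", "tiv_mm3"),
    fwe_alpha = 0.05,
    gpr_confounds = c("age", "sex", "tiv_mm3", "liv_mm3"),
    n_perm = 199L,
    run_glm = TRUE,
    run_gpr = TRUE
  )
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_cfg(cfg, modify), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with any subset of the [pipeline_config()] fields
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

# "corrupted truth" tissue maps: the probability maps a naive T1-driven
# segmentation would produce on this subject -- WMH and LI rims absorbed
# into GM, gliotic cores into CSF
corrupted_truth_tpms <- function(subj) {
  lab <- subj$labels$data
  wmh <- subj$wmh$data > 0 | (subj$li$data > 0 & subj$li_core$data == 0)
  core <- subj$li_core$data > 0
  gm <- (lab == 1 & !core) | wmh
  csf <- (lab == 0 & !wmh) | core
  wm <- lab == 2 & !wmh & !core
  tpm_set(list(gm = vol_like(subj$t1, gm * 1),
               wm = vol_like(subj$t1, wm * 1),
               csf = vol_like(subj$t1, csf * 1)))
}

# two-pass EM segmentation of one subject; returns 4-class native tpms
segment_subject_em <- function(subj, priors = NULL, seed = 1L) {
  mask <- vol_like(subj$t1, array(1, dim(subj$t1$data)))
  if (is.null(priors)) {
    fit <- fit_mixture(list(t1 = subj$t1), mask, K = 3, seed = seed)
    post <- posterior_maps(fit, list(t1 = subj$t1), mask = mask)
    # classes ordered by T1 mean: csf < gm < wm
    names(post$maps) <- c("csf", "gm", "wm")[order(order(fit$means[, 1]))]
    tpm_set(post$maps[c("gm", "wm", "csf")])
  } else {
    # initial class means from the prior-weighted data moments; the rare
    # WMH class is seeded from the brightest FLAIR voxels inside WM support
    X <- cbind(as.numeric(subj$t1$data), as.numeric(subj$flair$data))
    P <- vapply(priors$maps, function(m) as.numeric(m$data), numeric(nrow(X)))
    init <- t(vapply(seq_len(ncol(P)), function(k) {
      w <- P[, k]
      colSums(X * w) / max(sum(w), 1e-9)
    }, numeric(2)))
    icovs <- lapply(seq_len(ncol(P)), function(k) {
      w <- P[, k]
      xc <- sweep(X, 2, init[k, ])
      crossprod(xc * sqrt(w)) / max(sum(w), 1e-9)
    })
    wm_sup <- P[, "wm"] + (if ("wmh" %in% colnames(P)) P[, "wmh"] else 0)
    cand <- which(wm_sup > 0.2)
    kw <- which(names(priors$maps) == "wmh")
    if (length(kw) == 1 && length(cand) > 50) {
      bright <- cand[X[cand, 2] >= stats::quantile(X[cand, 2], 0.995)]
      init[kw, ] <- colMeans(X[bright, , drop = FALSE])
      # a tight covariance keeps the lesion class from swallowing the
      # normal-WM intensity tail
      icovs[[kw]] <- stats::cov(X[bright, , drop = FALSE])
    }
    fit <- fit_mixture(list(t1 = subj$t1, flair = subj$flair), mask,
                       priors = priors, seed = seed, init_means = init,
                       init_covs = icovs)
    out <- posterior_maps(fit, list(t1 = subj$t1, flair = subj$flair),
                          priors = priors, mask = mask)
    attr(out, "fit") <- fit
    out
  }
}

# a fitted lesion class must actually be FLAIR-hyperintense relative to WM;
# otherwise the subject is treated as lesion-free (the class has latched
# onto the normal-WM intensity tail)
wmh_class_is_hyperintense <- function(fit, flair_channel = 2L) {
  kw <- which(fit$class_names == "wmh")
  km <- which(fit$class_names == "wm")
  if (length(kw) == 0 || length(km) == 0) return(TRUE)
  wm_sd <- sqrt(fit$covs[[km]][flair_channel, flair_channel])
  fit$means[kw, flair_channel] > fit$means[km, flair_channel] + 3 * wm_sd
}

#' Run the full lesion-aware morphometry pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, segments each subject, applies the
#' lesion repair step, builds a group template, produces modulated GM and
#' warped-weighted cortical-thickness maps, and runs the voxel-wise GLM
#' (negative lesion-load contrast, peak-FWE corrected) and the kernel GPR
#' prediction of lesion load.  Every stage honours the step toggles in the
#' configuration; when `out_dir` is given all volumes, tables and a
#' manifest (configuration, seeds, package version, input hashes) are
#' written there.
#'
#' @param config a [pipeline_config()]
#' @param cohort_data optional precomputed result of [make_cohort()]
#' @param out_dir optional output directory
#' @return list with `table` (cohort covariates incl. measured volumes),
#'   `glm` (per-map-type t/p summaries), `gpr` (prediction reports),
#'   `maps`, `thickness`, `repaired`, `velocities`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(), cohort_data = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cs <- do.call(cohort_spec, c(config$cohort,
                               list(master_seed = config$seed)))
  ph <- do.call(phantom_spec, config$phantom)
  ls <- do.call(lesion_spec, config$lesions)
  im <- do.call(intensity_model, config$intensity)
  if (is.null(cohort_data))
    cohort_data <- make_cohort(cs, ph, ls, im)
  tab <- cohort_data$table
  subjects <- cohort_data$subjects
  n <- nrow(tab)

  ## --- segmentation + repair (native space) ------------------------------
  repaired <- vector("list", n)
  wmh_masks <- vector("list", n)
  li_masks <- lapply(subjects, function(s) s$li)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    if (config$segmentation == "truth") {
      tp <- corrupted_truth_tpms(s)
      wmh_masks[[i]] <- s$wmh
    } else {
      tp0 <- segment_subject_em(s, seed = config$seed + i)
      # population priors from the cohort's initial segmentations are built
      # below; the first EM pass is prior-free
      repaired[[i]] <- tp0
    }
  }
  if (config$segmentation == "em") {
    pop <- build_population_tpms(repaired, smooth_fwhm_mm = config$smooth_fwhm_mm)
    # WMH prior: a white-matter-supported fraction (no lesion atlas exists
    # for the phantom population; lesions live in WM)
    wmh_prior <- vol_like(pop$maps$wm, 0.25 * pop$maps$wm$data)
    pr_maps <- list(gm = pop$maps$gm, wm = vol_like(pop$maps$wm, 0.75 * pop$maps$wm$data),
                    csf = pop$maps$csf, wmh = wmh_prior)
    priors <- tpm_set(pr_maps)
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      seg <- segment_subject_em(s, priors = priors, seed = config$seed + i)
      wmh_masks[[i]] <- if (wmh_class_is_hyperintense(attr(seg, "fit")))
        binarise(seg$maps$wmh, config$thresholds$wmh)
      else
        vol_like(seg$maps$wmh, array(0, dim(seg$maps$wmh$data)))
      repaired[[i]] <- tpm_set(seg$maps[c("gm", "wm", "csf")])
    }
  } else {
    for (i in seq_len(n)) repaired[[i]] <- corrupted_truth_tpms(subjects[[i]])
  }
  unrepaired <- repaired
  if (isTRUE(config$repair)) {
    for (i in seq_len(n)) {
      rw <- repair_wmh(repaired[[i]]$maps$gm, repaired[[i]]$maps$wm, wmh_masks[[i]])
      repaired[[i]]$maps$gm <- rw$gm
      repaired[[i]]$maps$wm <- rw$wm
    }
    consensus <- consensus_li_classes(li_masks, repaired)
    for (i in seq_len(n)) {
      repaired[[i]] <- repair_li(repaired[[i]]$maps$gm, repaired[[i]]$maps$wm,
                                 repaired[[i]]$maps$csf, li_masks[[i]], consensus)
    }
  }
  # apply the segmentation-derived brain mask; removed mass becomes CSF
  if (isTRUE(config$repair)) {
    for (i in seq_len(n)) {
      ss <- skull_strip(subjects[[i]]$t1, repaired[[i]],
                        threshold = config$thresholds$skull_strip)
      repaired[[i]] <- apply_brain_mask(repaired[[i]], ss$mask)
    }
  }
  tab$tiv_mm3 <- NA_real_
  for (i in seq_len(n)) {
    vr <- compute_volumes(repaired[[i]], wmh_masks[[i]], li_masks[[i]],
                          tiv_threshold = config$thresholds$tiv)
    tab$wmhv_mm3[i] <- vr$wmhv_mm3
    tab$liv_mm3[i] <- vr$liv_mm3
    tab$tiv_mm3[i] <- vr$tiv_mm3
  }

  ## --- group space --------------------------------------------------------
  ref <- repaired[[1]]$maps$gm
  identity_phi <- function() {
    deformation_field(lapply(1:3, function(j) array(0, dim(ref$data))),
                      ref$affine, dim(ref$data), "group")
  }
  if (config$registration == "full") {
    tmpl <- build_template(repaired, n_outer = config$template_n_outer,
                           params = do.call(reg_params, config$reg))
    phis <- lapply(tmpl$velocities, exp_velocity)
    velocities <- tmpl$velocities
  } else {
    phis <- replicate(n, identity_phi(), simplify = FALSE)
    velocities <- NULL
  }
  maps_gm <- vector("list", n)
  thick_maps <- vector("list", n)
  vb <- do.call(vbct_params, config$vbct)
  for (i in seq_len(n)) {
    wgm <- warp_volume(repaired[[i]]$maps$gm, phis[[i]], order = 1L)
    jac <- jacobian_det(phis[[i]])
    maps_gm[[i]] <- gaussian_smooth(modulate(wgm, jac), config$smooth_fwhm_mm)
    th <- vbct(repaired[[i]], vb)
    wth <- warp_volume(th, phis[[i]], order = 1L)
    weight <- modulate(wgm, jac)
    # one-sided Jacobian stencils can dip below zero on the FOV rim
    weight$data <- pmax(weight$data, 0)
    thick_maps[[i]] <- warped_weighted_smooth(wth, weight, config$smooth_fwhm_mm)
  }

  ## --- voxel-wise GLM ------------------------------------------------------
  glm_out <- NULL
  mean_gm <- Reduce(`+`, lapply(maps_gm, function(m) m$data)) / n
  gm_mask <- vol_like(ref, (mean_gm >= 0.1) * 1)
  if (isTRUE(config$run_glm)) {
    X <- design_matrix(tab, config$glm_covariates)
    cvec <- as.numeric(colnames(X) == "wmhv_mm3") * -1
    map_sets <- list(gm = maps_gm, thickness = thick_maps)
    glm_out <- lapply(names(map_sets), function(kind) {
      maps <- map_sets[[kind]]
      msk <- if (kind == "thickness") {
        support <- Reduce(`+`, lapply(maps, function(m) (m$data > 0) * 1)) / n
        vol_like(ref, (support >= 0.1 & gm_mask$data > 0) * 1)
      } else gm_mask
      g <- fit_glm(maps, X, msk)
      tm <- t_contrast(g, cvec, name = "wmhv_negative")
      sm <- estimate_smoothness(g)
      tm$fwhm_mm <- sm$fwhm_mm
      tm$resels <- sm$resels
      p <- rft_peak_fwe(tm)
      list(tmap = tm, fwe_p = p, fwhm_mm = sm$fwhm_mm, resels = sm$resels,
           n_sig = sum(p$data < config$fwe_alpha))
    })
    names(glm_out) <- names(map_sets)
  }

  ## --- GPR prediction of lesion load --------------------------------------
  gpr_out <- NULL
  if (isTRUE(config$run_gpr)) {
    conf <- as.matrix(tab[, config$gpr_confounds, drop = FALSE])
    gpr_out <- lapply(list(gm = maps_gm, thickness = thick_maps), function(maps) {
      km <- build_linear_kernel(maps, gm_mask)
      rep <- loo_cv(km, tab$wmhv_mm3, confounds = conf)
      perm <- permutation_significance(km, tab$wmhv_mm3, confounds = conf,
                                       n_perm = config$n_perm,
                                       seed = config$seed)
      rep$permutation_p <- perm$p
      kmr <- residualise_confounds(km, conf)
      model <- gpr_fit(kmr, tab$wmhv_mm3)
      list(report = rep, weight_map = weight_map(model, kmr))
    })
  }

  out <- list(table = tab, glm = glm_out, gpr = gpr_out, maps = maps_gm,
              thickness = thick_maps, repaired = repaired,
              unrepaired = unrepaired, wmh_masks = wmh_masks,
              velocities = velocities, gm_mask = gm_mask, config = config)
  if (!is.null(out_dir)) write_run_outputs(out, cohort_data, out_dir)
  invisible(out)
}

# persist a pipeline run: volumes, tables, summary JSON and a manifest
write_run_outputs <- function(out, cohort_data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$table, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  n <- nrow(out$table)
  for (i in seq_len(n)) {
    sd <- file.path(out_dir, out$table$subject_id[i])
    dir.create(sd, showWarnings = FALSE)
    write_volume(cohort_data$subjects[[i]]$t1, file.path(sd, "t1.nii.gz"))
    write_volume(cohort_data$subjects[[i]]$flair, file.path(sd, "flair.nii.gz"))
    for (cl in names(out$repaired[[i]]$maps))
      write_volume(out$repaired[[i]]$maps[[cl]],
                   file.path(sd, sprintf("repaired_%s.nii.gz", cl)))
    write_volume(out$maps[[i]], file.path(sd, "gm_modulated_smoothed.nii.gz"))
    write_volume(out$thickness[[i]], file.path(sd, "thickness_smoothed.nii.gz"))
  }
  summary <- list(
    n_subjects = n,
    glm = if (!is.null(out$glm)) lapply(out$glm, function(g)
      list(n_sig = g$n_sig, fwhm_mm = g$fwhm_mm)) else NULL,
    gpr = if (!is.null(out$gpr)) lapply(out$gpr, function(g)
      list(pearson_r = g$report$pearson_r, r_squared = g$report$r_squared,
           rmse = g$report$rmse, permutation_p = g$report$permutation_p))
      else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lesionmorph")),
    seed = out$config$seed,
    config = unclass(out$config),
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
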