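#' Phantom geometry specification
#'
#' Describes the noise-free anatomy of a synthetic subject: a white-matter
#' core wrapped in a grey-matter shell of known cortical thickness,
#' surrounded by CSF/background.  Two geometries are supported: a
#' concentric `sphere_shell` (WM ball of radius `wm_radius_mm`, GM shell of
#' thickness `gm_thickness_mm`) and an axis-aligned `flat_slab` (WM slab of
#' thickness `wm_radius_mm` topped by a GM slab, stacked along the third
#' axis), which has an exactly known thickness everywhere and serves as the
#' analytic oracle for the cortical-thickness solver.
#'
#' @param grid_shape length-3 integer vector of voxels per axis
#' @param voxel_size_mm isotropic voxel size in mm
#' @param wm_radius_mm WM sphere radius (or WM slab thickness) in mm
#' @param gm_thickness_mm true cortical thickness of the GM shell in mm
#' @param geometry `"sphere_shell"` or `"flat_slab"`
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), voxel_size_mm = 2,
                         wm_radius_mm = 30, gm_thickness_mm = 4,
                         geometry = c("sphere_shell", "flat_slab")) {
  geometry <- match.arg(geometry)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  stop_if(gm_thickness_mm <= 0, "gm_thickness_mm must be > 0")
  stop_if(wm_radius_mm <= 0, "wm_radius_mm must be > 0")
  h <- voxel_size_mm
  margin <- 3 * h
  if (geometry == "sphere_shell") {
    half_extent <- min(grid_shape) * h / 2
    stop_if(wm_radius_mm + gm_thickness_mm + margin > half_extent,
            "phantom does not fit in the grid with a 3-voxel CSF margin")
  } else {
    extent <- grid_shape[3] * h
    stop_if(wm_radius_mm + gm_thickness_mm + 2 * margin > extent,
            "slab phantom does not fit in the grid with 3-voxel CSF margins")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 wm_radius_mm = wm_radius_mm, gm_thickness_mm = gm_thickness_mm,
                 geometry = geometry),
            class = "phantom_spec")
}

#' Lesion specification for a synthetic subject
#'
#' @param n_wmh number of white-matter-hyperintensity lesions
#' @param wmh_radius_mm_range interval from which WMH radii are drawn
#' @param n_li number of lacunar infarcts
#' @param li_radius_mm_range interval from which LI radii are drawn
#' @param li_gliosis_fraction volume fraction of each LI rendered as
#'   CSF-like gliosis (the innermost core)
#' @return a `lesion_spec` object
#' @export
lesion_spec <- function(n_wmh = 5, wmh_radius_mm_range = c(3, 6),
                        n_li = 2, li_radius_mm_range = c(3, 5),
                        li_gliosis_fraction = 0.5) {
  stop_if(n_wmh < 0 || n_li < 0, "lesion counts must be >= 0")
  stop_if(li_gliosis_fraction < 0 || li_gliosis_fraction > 1,
          "li_gliosis_fraction must be in [0, 1]")
  structure(list(n_wmh = n_wmh, wmh_radius_mm_range = sort(wmh_radius_mm_range),
                 n_li = n_li, li_radius_mm_range = sort(li_radius_mm_range),
                 li_gliosis_fraction = li_gliosis_fraction),
            class = "lesion_spec")
}

#' Two-channel intensity model for phantom rendering
#'
#' Per-class mean vectors (T1, FLAIR) and 2x2 covariances for the five
#' rendered classes.  The defaults encode the contrast pattern that makes
#' naive T1-only segmentation fail on small-vessel-disease brains: WMH sits
#' between GM and WM on T1 (so it is absorbed into GM) while being the
#' brightest class on FLAIR, and gliosis inside lacunar infarcts is
#' CSF-like on T1.  Intensities are in arbitrary units; no quantitative
#' lesion intensity statistics exist for the source cohort, so the defaults
#' are free parameters of the generator.
#'
#' @param means 5x2 matrix of class means, rows `csf, gm, wm, wmh, gliosis`,
#'   columns `t1, flair`
#' @param covs list of five 2x2 positive-semi-definite covariance matrices
#'   (same order)
#' @param bias_field_amplitude relative amplitude of a multiplicative
#'   smooth bias field (0 disables it)
#' @param noise_seed integer seed for the rendering noise
#' @return an `intensity_model` object
#' @export
intensity_model <- function(means = NULL, covs = NULL,
                            bias_field_amplitude = 0, noise_seed = 1L) {
  classes <- c("csf", "gm", "wm", "wmh", "gliosis")
  if (is.null(means)) {
    means <- rbind(csf = c(25, 20), gm = c(60, 60), wm = c(90, 50),
                   wmh = c(70, 95), gliosis = c(32, 45))
    colnames(means) <- c("t1", "flair")
  }
  means <- as.matrix(means)
  stop_if(nrow(means) != 5 || ncol(means) != 2, "means must be a 5x2 matrix")
  rownames(means) <- classes
  if (is.null(covs)) covs <- rep(list(diag(c(25, 25))), 5)
  stop_if(length(covs) != 5, "covs must list five 2x2 matrices")
  for (S in covs) {
    stop_if(max(abs(S - t(S))) > 1e-8, "class covariance not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    stop_if(min(ev) < -1e-8, "class covariance not positive semi-definite")
  }
  names(covs) <- classes
  t1 <- means[, 1]
  stop_if(t1["wmh"] <= min(t1["gm"], t1["wm"]) || t1["wmh"] >= max(t1["gm"], t1["wm"]),
          "WMH T1 mean must lie between the GM and WM means")
  stop_if(which.max(means[, 2]) != 4L, "WMH must have the largest FLAIR mean")
  structure(list(means = means, covs = covs,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_seed = as.integer(noise_seed)),
            class = "intensity_model")
}

#' Cohort specification for synthetic studies
#'
#' Encodes the association the downstream analysis is designed to detect:
#' cortical thickness declines linearly with white-matter lesion load at
#' `thinning_coefficient` mm per 10,000 mm^3 of WMH volume.
#'
#' @param n_subjects number of subjects (>= 3)
#' @param age_mean,age_sd age distribution in years
#' @param sex_ratio probability of sex code 1
#' @param wmhv_range_mm3 interval of target WMH loads (uniform draw)
#' @param thinning_coefficient_mm_per_10k mm of GM thickness lost per
#'   10,000 mm^3 of WMH volume
#' @param warp_amplitude_mm root-mean-square amplitude of the per-subject
#'   random smooth deformation
#' @param master_seed integer seed controlling the whole cohort
#' @return a `cohort_spec` object
#' @export
cohort_spec <- function(n_subjects = 20, age_mean = 70, age_sd = 10,
                        sex_ratio = 0.5, wmhv_range_mm3 = c(0, 40000),
                        thinning_coefficient_mm_per_10k = 0.5,
                        warp_amplitude_mm = 1.5, master_seed = 42L) {
  stop_if(n_subjects < 3, "n_subjects must be >= 3")
  structure(list(n_subjects = as.integer(n_subjects), age_mean = age_mean,
                 age_sd = age_sd, sex_ratio = sex_ratio,
                 wmhv_range_mm3 = sort(wmhv_range_mm3),
                 thinning_coefficient_mm_per_10k = thinning_coefficient_mm_per_10k,
                 warp_amplitude_mm = warp_amplitude_mm,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# run expr with a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# voxel-centre coordinates (mm) along each axis: (k + 0.5) * h, 0-based k
axis_coords <- function(spec) {
  lapply(1:3, function(ax) (seq_len(spec$grid_shape[ax]) - 0.5) * spec$voxel_size_mm)
}

#' Build the noise-free tissue label map of a phantom
#'
#' Labels are 0 (background/CSF), 1 (GM), 2 (WM).  For the sphere-shell
#' geometry, GM occupies `wm_radius <= ||x - c|| < wm_radius + gm_thickness`
#' measured at voxel centres; for the flat slab the tissue interfaces are
#' axis-aligned planes.
#'
#' @param spec a [phantom_spec]
#' @return a [volume] of integer labels
#' @export
make_labelmap <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  h <- spec$voxel_size_mm
  co <- axis_coords(spec)
  lab <- array(0, d)
  if (spec$geometry == "sphere_shell") {
    centre <- d * h / 2
    r2 <- outer(outer((co[[1]] - centre[1])^2, (co[[2]] - centre[2])^2, `+`),
                (co[[3]] - centre[3])^2, `+`)
    r <- sqrt(r2)
    lab[r < spec$wm_radius_mm] <- 2
    lab[r >= spec$wm_radius_mm & r < spec$wm_radius_mm + spec$gm_thickness_mm] <- 1
  } else {
    z0 <- 3 * h                      # bottom CSF margin
    z <- co[[3]]
    wm_cols <- z >= z0 & z < z0 + spec$wm_radius_mm
    gm_cols <- z >= z0 + spec$wm_radius_mm &
      z < z0 + spec$wm_radius_mm + spec$gm_thickness_mm
    lab[, , wm_cols] <- 2
    lab[, , gm_cols] <- 1
  }
  volume(lab, voxel_size_mm = h)
}

# voxel offsets (rows) covering a ball of given radius in voxels
ball_offsets <- function(radius_vox) {
  r <- ceiling(radius_vox)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius_vox^2, , drop = FALSE]
  as.matrix(g)
}

#' Implant spherical WMH and lacunar-infarct lesions into the WM
#'
#' Lesion centres are drawn among WM voxels such that the lesion sphere is
#' (as far as possible) contained in WM; the resulting masks are clipped to
#' WM and kept mutually disjoint.  Each lacunar infarct additionally gets a
#' central gliotic core holding `li_gliosis_fraction` of its volume.
#'
#' @param labels label [volume] from [make_labelmap()]
#' @param lesions a [lesion_spec]
#' @param seed integer seed; the same seed reproduces the masks exactly
#' @param wmh_target_mm3 optional target WMH volume; when given, WMH
#'   lesions are added until the realised mask volume reaches it
#'   (overrides `n_wmh`)
#' @return list with `labels`, binary-mask volumes `wmh`, `li`, `li_core`
#' @export
implant_lesions <- function(labels, lesions, seed = 1L, wmh_target_mm3 = NULL) {
  stopifnot(inherits(lesions, "lesion_spec"))
  d <- dim(labels$data)
  h <- voxel_size(labels)[1]
  vv <- voxel_volume(labels)
  wm <- labels$data == 2
  n_wm <- sum(wm)
  stop_if(n_wm == 0, "label map contains no WM")
  with_seed(seed, {
    occupied <- array(FALSE, d)
    place_sphere <- function(radius_mm, forbid) {
      off <- ball_offsets(radius_mm / h)
      cand <- which(wm & !forbid)
      stop_if(length(cand) == 0, "no WM voxels left for lesion placement")
      best <- NULL; best_frac <- -1
      for (try in 1:60) {
        ci <- cand[sample.int(length(cand), 1L)]
        cc <- arrayInd(ci, d)
        vox <- sweep(off, 2, as.integer(cc), `+`)
        keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
          vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
        vox <- vox[keep, , drop = FALSE]
        lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
        ok <- wm[lin] & !forbid[lin]
        frac <- mean(ok)
        if (frac > best_frac) { best_frac <- frac; best <- lin[ok]; best_centre <- ci }
        if (frac > 0.999) break
      }
      list(voxels = best, centre = best_centre)
    }
    wmh_mask <- array(FALSE, d)
    li_mask <- array(FALSE, d)
    li_core <- array(FALSE, d)
    rr <- lesions$wmh_radius_mm_range
    mean_lesion_vol <- if (diff(rr) > 0)
      (pi / 3) * (rr[2]^4 - rr[1]^4) / (rr[2] - rr[1]) else (4 / 3) * pi * rr[1]^3
    stop_if(!is.null(wmh_target_mm3) && wmh_target_mm3 > 0.6 * n_wm * vv,
            "requested WMH volume exceeds the available white matter")
    stop_if(is.null(wmh_target_mm3) &&
              lesions$n_wmh * mean_lesion_vol > 0.9 * n_wm * vv,
            "requested WMH volume exceeds the available white matter")
    n_wmh <- if (is.null(wmh_target_mm3)) lesions$n_wmh else
      max(0L, 4L * as.integer(ceiling(wmh_target_mm3 / mean_lesion_vol)))
    placed_vol <- 0
    for (i in seq_len(n_wmh)) {
      if (!is.null(wmh_target_mm3) &&
          placed_vol + mean_lesion_vol / 2 >= wmh_target_mm3) break
      r <- stats::runif(1, rr[1], rr[2])
      sp <- place_sphere(r, occupied)
      wmh_mask[sp$voxels] <- TRUE
      occupied[sp$voxels] <- TRUE
      placed_vol <- sum(wmh_mask) * vv
    }
    for (i in seq_len(lesions$n_li)) {
      r <- stats::runif(1, lesions$li_radius_mm_range[1], lesions$li_radius_mm_range[2])
      sp <- place_sphere(r, occupied)
      li_mask[sp$voxels] <- TRUE
      occupied[sp$voxels] <- TRUE
      # gliotic core: innermost sub-sphere holding the requested fraction
      core_r <- r * lesions$li_gliosis_fraction^(1 / 3)
      cc <- arrayInd(sp$centre, d)
      off <- ball_offsets(core_r / h)
      vox <- sweep(off, 2, as.integer(cc), `+`)
      keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
        vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
      vox <- vox[keep, , drop = FALSE]
      lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
      li_core[intersect(lin, sp$voxels)] <- TRUE
    }
  })
  list(labels = labels,
       wmh = vol_like(labels, wmh_mask * 1),
       li = vol_like(labels, li_mask * 1),
       li_core = vol_like(labels, li_core * 1))
}

#' Render T1 and FLAIR intensities from a label map and lesion masks
#'
#' Each voxel draws from the bivariate Gaussian of its class: CSF, GM and
#' WM from the label map; WMH voxels (and the non-gliotic rim of lacunar
#' infarcts) from the WMH class; gliotic LI cores from the gliosis class.
#' An optional multiplicative smooth bias field is applied to both
#' channels.
#'
#' @param labels label [volume]
#' @param wmh,li binary WMH / LI mask volumes
#' @param model an [intensity_model]
#' @param li_core optional gliosis-core mask (defaults to empty)
#' @param seed rendering seed; defaults to `model$noise_seed`
#' @return list of [volume]s `t1` and `flair`
#' @export
render_intensities <- function(labels, wmh, li, model, li_core = NULL,
                               seed = NULL) {
  stopifnot(inherits(model, "intensity_model"))
  check_grid(labels, wmh, li)
  d <- dim(labels$data)
  if (is.null(li_core)) li_core <- vol_like(labels, array(0, d))
  seed <- seed %||% model$noise_seed
  cls <- array(1L, d)                       # 1 csf
  cls[labels$data == 1] <- 2L               # gm
  cls[labels$data == 2] <- 3L               # wm
  cls[wmh$data > 0 | li$data > 0] <- 4L     # wmh (incl. LI rim)
  cls[li_core$data > 0] <- 5L               # gliosis
  t1 <- array(0, d); flair <- array(0, d)
  with_seed(seed, {
    for (k in 1:5) {
      idx <- which(cls == k)
      if (length(idx) == 0) next
      mu <- model$means[k, ]
      S <- model$covs[[k]]
      if (max(abs(S)) < 1e-12) {
        x <- matrix(rep(mu, each = length(idx)), ncol = 2)
      } else {
        L <- chol(S + diag(1e-12, 2))
        z <- matrix(stats::rnorm(2 * length(idx)), ncol = 2)
        x <- sweep(z %*% L, 2, mu, `+`)
      }
      t1[idx] <- x[, 1]
      flair[idx] <- x[, 2]
    }
    if (model$bias_field_amplitude > 0) {
      vs <- voxel_size(labels)
      b <- array(stats::rnorm(prod(d)), d)
      b <- smooth_array(b, 40 / (2.355 * vs))   # ~40 mm FWHM modulation
      b <- b / stats::sd(b)
      b <- 1 + model$bias_field_amplitude * b
      b[b < 0.1] <- 0.1
      t1 <- t1 * b
      flair <- flair * b
    }
  })
  list(t1 = vol_like(labels, t1), flair = vol_like(labels, flair))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject age, sex and target WMH load, thins each subject's GM
#' shell by `thinning_coefficient * WMHV / 10000` mm before lesioning,
#' implants lesions to the target load, applies a random smooth
#' diffeomorphic warp, and renders T1/FLAIR.  The recorded `wmhv_mm3` and
#' `liv_mm3` are measured from the realised truth masks (after warping), so
#' they agree with the masks to the voxel.
#'
#' @param cohort a [cohort_spec]
#' @param phantom a [phantom_spec] giving the base anatomy
#' @param lesions a [lesion_spec] (WMH count is overridden by the load)
#' @param model an [intensity_model]
#' @param out_dir optional directory; when given, per-subject NIfTI files
#'   and `cohort.csv` are written there
#' @return list with `table` (data.frame: subject_id, age, sex, wmhv_mm3,
#'   liv_mm3, gm_thickness_mm) and `subjects` (list of per-subject volumes:
#'   t1, flair, labels, wmh, li, li_core, warp)
#' @export
make_cohort <- function(cohort, phantom = phantom_spec(),
                        lesions = lesion_spec(), model = intensity_model(),
                        out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_subjects
  draws <- with_seed(cohort$master_seed, {
    list(seeds = sample.int(2^31 - 2, n),
         age = stats::rnorm(n, cohort$age_mean, cohort$age_sd),
         sex = stats::rbinom(n, 1, cohort$sex_ratio),
         wmhv_target = stats::runif(n, cohort$wmhv_range_mm3[1],
                                    cohort$wmhv_range_mm3[2]))
  })
  thin <- cohort$thinning_coefficient_mm_per_10k * draws$wmhv_target / 10000
  thickness <- phantom$gm_thickness_mm - thin
  stop_if(any(thickness < 0.5),
          "thinning drives GM thickness below 0.5 mm; reduce the load range or coefficient")
  subjects <- vector("list", n)
  tab <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                    age = round(draws$age, 1), sex = draws$sex,
                    wmhv_mm3 = NA_real_, liv_mm3 = NA_real_,
                    gm_thickness_mm = thickness)
  for (i in seq_len(n)) {
    spec_i <- phantom
    spec_i$gm_thickness_mm <- thickness[i]
    lab <- make_labelmap(spec_i)
    les <- implant_lesions(lab, lesions, seed = draws$seeds[i],
                           wmh_target_mm3 = draws$wmhv_target[i])
    if (cohort$warp_amplitude_mm > 0) {
      v <- random_velocity(lab, cohort$warp_amplitude_mm,
                           seed = draws$seeds[i] %% (2^31 - 2) + 1L)
      # rendering warps do not need the tight inverse-consistency step
      phi <- exp_velocity(v, step = 0.25)
      lab <- warp_volume(les$labels, phi, order = 0L)
      wmh <- warp_mask(les$wmh, phi)
      li <- warp_mask(les$li, phi)
      core <- warp_mask(les$li_core, phi)
      core$data <- core$data * li$data     # keep core inside LI after NN warping
    } else {
      phi <- NULL
      wmh <- les$wmh; li <- les$li; core <- les$li_core
    }
    img <- render_intensities(lab, wmh, li, model, li_core = core,
                              seed = draws$seeds[i])
    vv <- voxel_volume(lab)
    tab$wmhv_mm3[i] <- sum(wmh$data) * vv
    tab$liv_mm3[i] <- sum(li$data) * vv
    subjects[[i]] <- list(t1 = img$t1, flair = img$flair, labels = lab,
                          wmh = wmh, li = li, li_core = core, warp = phi)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      sd <- file.path(out_dir, tab$subject_id[i])
      dir.create(sd, showWarnings = FALSE)
      write_volume(subjects[[i]]$t1, file.path(sd, "t1.nii.gz"))
      write_volume(subjects[[i]]$flair, file.path(sd, "flair.nii.gz"))
      write_volume(subjects[[i]]$wmh, file.path(sd, "wmh_truth.nii.gz"))
      write_volume(subjects[[i]]$li, file.path(sd, "li_truth.nii.gz"))
    }
    utils::write.csv(tab[, c("subject_id", "age", "sex", "wmhv_mm3", "liv_mm3")],
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
  }
  list(table = tab, subjects = subjects)
}

#' Random smooth velocity field for subject-level deformations
#'
#' White noise smoothed to ~3x the voxel size is scaled to the requested
#' root-mean-square displacement amplitude and tapered to zero near the
#' grid boundary, then exponentiated by [exp_velocity()] so every subject
#' warp is a diffeomorphism.
#'
#' @param vol a [volume] defining the grid
#' @param amplitude_mm RMS displacement in mm
#' @param seed integer seed
#' @param fwhm_mm smoothness of the field (default 6 voxels in mm)
#' @return a `velocity_field` object
#' @export
random_velocity <- function(vol, amplitude_mm, seed = 1L, fwhm_mm = NULL) {
  d <- dim(vol$data)
  vs <- voxel_size(vol)
  fwhm_mm <- fwhm_mm %||% (6 * mean(vs))
  taper <- taper_mask(d)
  comps <- with_seed(seed, lapply(1:3, function(ax) {
    f <- smooth_array(array(stats::rnorm(prod(d)), d), fwhm_mm / (2.355 * vs))
    f * taper
  }))
  rms <- sqrt(mean(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2))
  if (rms > 0) comps <- lapply(comps, function(f) f * amplitude_mm / rms)
  velocity_field(comps, vol)
}

# smoothstep taper to zero over a 6-voxel rim (keeps the field curvature
# low near the edge so scaling-and-squaring stays accurate there)
taper_mask <- function(d) {
  w <- lapply(d, function(n) {
    x <- pmin(1, pmin(seq_len(n) - 1, n - seq_len(n)) / 6)
    x^2 * (3 - 2 * x)
  })
  outer(outer(w[[1]], w[[2]]), w[[3]])
}
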