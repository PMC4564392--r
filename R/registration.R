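#' Stationary velocity field
#'
#' Generator of a diffeomorphic warp: three displacement-rate components in
#' mm on the grid of a reference volume.  Exponentiating a velocity field
#' with [exp_velocity()] yields a deformation whose inverse is generated by
#' the negated field, so invertibility is guaranteed by construction.
#'
#' @param comps list of three 3-D arrays (mm)
#' @param ref a [volume] defining the grid
#' @return a `velocity_field`
#' @export
velocity_field <- function(comps, ref) {
  stop_if(length(comps) != 3L, "a velocity field needs three components")
  for (f in comps) {
    stop_if(!identical(dim(f), dim(ref$data)), "component grid mismatch")
    stop_if(!all(is.finite(f)), "velocity field must be finite")
  }
  structure(list(comps = comps, affine = ref$affine, dim = dim(ref$data),
                 space = ref$space),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  mx <- sqrt(max(x$comps[[1]]^2 + x$comps[[2]]^2 + x$comps[[3]]^2))
  cat(sprintf("velocity_field: %d x %d x %d, max |v| = %.3g mm\n",
              x$dim[1], x$dim[2], x$dim[3], mx))
  invisible(x)
}

# deformation field: per-voxel source coordinate offsets in voxel units on
# the target grid; the mapping is source_voxel = target_voxel + disp
deformation_field <- function(disp, affine, dims, space = "native") {
  structure(list(disp = disp, affine = affine, dim = dims, space = space),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mx <- sqrt(max(x$disp[[1]]^2 + x$disp[[2]]^2 + x$disp[[3]]^2))
  cat(sprintf("deformation_field: %d x %d x %d, max displacement = %.3g voxels\n",
              x$dim[1], x$dim[2], x$dim[3], mx))
  invisible(x)
}

# sample the three displacement components at (index + disp) and add;
# cubic B-spline sampling keeps the squaring error well below the
# trilinear discretisation floor
compose_disp <- function(a, b, dims, ig, order = 3L) {
  # returns displacement of phi_a o phi_b  (apply b first)
  coords <- cbind(ig[, 1] + as.numeric(b[[1]]),
                  ig[, 2] + as.numeric(b[[2]]),
                  ig[, 3] + as.numeric(b[[3]]))
  lapply(1:3, function(j) {
    aj <- as.numeric(a[[j]])
    if (order >= 2) aj <- cpp_bspline_prefilter(aj, dims, order)
    s <- cpp_sample3d(aj, dims, coords, as.integer(order))
    array(s + as.numeric(b[[j]]), dims)
  })
}

#' Exponentiate a stationary velocity field (scaling and squaring)
#'
#' The number of squarings K is chosen so the first-step displacement is
#' below `step` voxels; `exp_velocity(negate(v))` generates the inverse
#' warp.
#'
#' @param v a [velocity_field]
#' @param order interpolation degree used in the squaring compositions
#'   (cubic by default; 1 gives a faster, rougher exponential for inner
#'   optimisation loops)
#' @param step first-step displacement bound in voxels (controls the
#'   number of squarings)
#' @return a `deformation_field` on the same grid
#' @export
exp_velocity <- function(v, order = 3L, step = 0.0625) {
  stopifnot(inherits(v, "velocity_field"))
  vs <- sqrt(colSums(v$affine[1:3, 1:3]^2))
  u <- lapply(1:3, function(j) v$comps[[j]] / vs[j])
  maxd <- sqrt(max(u[[1]]^2 + u[[2]]^2 + u[[3]]^2))
  K <- if (maxd <= step) 0L else as.integer(ceiling(log2(maxd / step)))
  u <- lapply(u, function(f) f / 2^K)
  ig <- index_grid(v$dim)
  for (k in seq_len(K)) u <- compose_disp(u, u, v$dim, ig, order = order)
  deformation_field(u, v$affine, v$dim, v$space)
}

#' Negate a velocity field (generator of the inverse warp)
#' @param v a [velocity_field]
#' @export
negate <- function(v) {
  v$comps <- lapply(v$comps, function(f) -f)
  v
}

#' Compose two deformation fields on the same grid
#' @param a,b `deformation_field`s; the result applies `b` first
#' @return a `deformation_field`
#' @export
compose_deformations <- function(a, b) {
  stop_if(!identical(a$dim, b$dim), "deformation grids differ")
  ig <- index_grid(a$dim)
  deformation_field(compose_disp(a$disp, b$disp, a$dim, ig), a$affine, a$dim, a$space)
}

#' Pull a volume back through a deformation field
#'
#' @param vol source [volume]
#' @param phi a `deformation_field` whose grid is the target grid
#' @param order interpolation degree 0..4
#' @return warped [volume] on the grid of `phi`
#' @export
warp_volume <- function(vol, phi, order = 1L) {
  stopifnot(inherits(phi, "deformation_field"))
  stop_if(!identical(dim(vol$data), phi$dim),
          "volume and deformation grids differ")
  ig <- index_grid(phi$dim)
  coords <- cbind(ig[, 1] + as.numeric(phi$disp[[1]]),
                  ig[, 2] + as.numeric(phi$disp[[2]]),
                  ig[, 3] + as.numeric(phi$disp[[3]]))
  arr <- vol$data
  if (order >= 2) arr <- array(cpp_bspline_prefilter(as.numeric(arr), dim(arr), order), dim(arr))
  vals <- cpp_sample3d(as.numeric(arr), dim(vol$data), coords, as.integer(order))
  volume(array(vals, phi$dim), affine = phi$affine, space = phi$space)
}

#' Warp a binary mask (nearest neighbour, re-binarised)
#' @param mask binary mask [volume]
#' @param phi a `deformation_field`
#' @export
warp_mask <- function(mask, phi) {
  w <- warp_volume(mask, phi, order = 0L)
  vol_like(w, (w$data >= 0.5) * 1)
}

#' Jacobian determinant of a deformation field
#'
#' Central differences of the mapping in voxel units (one-sided at the
#' boundary); the identity map has determinant 1 everywhere, and any
#' deformation produced by [exp_velocity()] should be strictly positive.
#'
#' @param phi a `deformation_field`
#' @return [volume] of determinants
#' @export
jacobian_det <- function(phi) {
  d <- phi$dim
  J <- vector("list", 9)
  for (i in 1:3)
    for (j in 1:3) {
      g <- central_diff(phi$disp[[i]], j, 1)
      if (i == j) g <- g + 1
      J[[(i - 1) * 3 + j]] <- g
    }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  volume(det, affine = phi$affine, space = phi$space)
}

#' Jacobian-modulate a warped grey-matter map
#'
#' Voxel-wise product of the warped tissue map with the Jacobian
#' determinant of its warp, so that total tissue volume is preserved under
#' spatial normalisation.
#'
#' @param warped_gm warped GM probability [volume]
#' @param jac Jacobian determinant [volume]
#' @return modulated [volume]
#' @export
modulate <- function(warped_gm, jac) {
  check_grid(warped_gm, jac)
  vol_like(warped_gm, warped_gm$data * jac$data)
}

#' Warped-weighted smoothing of a thickness map
#'
#' Ratio smoothing `smooth(weight * thickness) / smooth(weight)`: averages
#' thickness within cortex (weight = warped GM probability times Jacobian)
#' without bleeding values across tissue boundaries.  Voxels where the
#' smoothed weight falls below `eps` are set to 0.
#'
#' @param thickness_warped warped thickness [volume] (mm)
#' @param weight non-negative weight [volume]
#' @param fwhm_mm smoothing kernel FWHM (default 6 mm)
#' @param eps support threshold on the smoothed weight
#' @return smoothed thickness [volume]
#' @export
warped_weighted_smooth <- function(thickness_warped, weight, fwhm_mm = 6,
                                   eps = 1e-3) {
  check_grid(thickness_warped, weight)
  stop_if(any(weight$data < 0), "weights must be non-negative")
  stop_if(all(weight$data == 0), "all-zero weight image")
  num <- gaussian_smooth(vol_like(weight, weight$data * thickness_warped$data), fwhm_mm)
  den <- gaussian_smooth(weight, fwhm_mm)
  out <- ifelse(den$data > eps, num$data / pmax(den$data, eps), 0)
  vol_like(thickness_warped, out)
}

#' Registration parameters
#'
#' @param n_scales multiresolution levels (coarsest factor `2^(n_scales-1)`)
#' @param iters_per_scale gradient-descent iterations at each level
#' @param smooth_fwhm_vox Gaussian FWHM (voxels) applied to each velocity
#'   update, acting as the regulariser
#' @param step0_vox initial update magnitude in voxels
#' @return parameter list
#' @export
reg_params <- function(n_scales = 3, iters_per_scale = 12,
                       smooth_fwhm_vox = 8, step0_vox = 2) {
  list(n_scales = n_scales, iters_per_scale = iters_per_scale,
       smooth_fwhm_vox = smooth_fwhm_vox, step0_vox = step0_vox)
}

# downsample a volume by an integer factor (trilinear at coarse centres)
downsample_vol <- function(vol, factor) {
  if (factor == 1) return(vol)
  d <- dim(vol$data)
  nd <- pmax(2L, as.integer(ceiling(d / factor)))
  scale <- diag(c(factor, factor, factor, 1))
  shift <- diag(4); shift[1:3, 4] <- (factor - 1) / 2
  taff <- vol$affine %*% shift %*% scale
  sm <- vol_like(vol, smooth_array(vol$data, rep(factor / 2, 3)))
  resample(sm, list(dim = nd, affine = taff), order = 1L)
}

# sum of squared differences between two sets of maps (lists of arrays)
ssd_maps <- function(a, b) sum(vapply(seq_along(a),
                                      function(i) sum((a[[i]] - b[[i]])^2), 0))

#' Diffeomorphic registration of one tissue-map set to another
#'
#' Minimises the multi-class sum of squared differences between the warped
#' moving maps and the fixed maps over a stationary velocity field, with
#' Gaussian-smoothed gradient updates and backtracking step control, across
#' a multiresolution pyramid.  Both map sets must share a grid (affine
#' pre-alignment is assumed).
#'
#' @param moving,fixed [tpm_set]s with the same classes and grid
#' @param params from [reg_params()]
#' @return a [velocity_field] with attribute `ssd_trace`: a list, one
#'   numeric vector of objective values per resolution level, each
#'   non-increasing
#' @export
register_pair <- function(moving, fixed, params = reg_params()) {
  stopifnot(inherits(moving, "tpm_set"), inherits(fixed, "tpm_set"))
  stop_if(!identical(names(moving$maps), names(fixed$maps)),
          "moving and fixed tissue-map sets have different classes")
  ref <- moving$maps[[1]]
  check_grid(ref, fixed$maps[[1]])
  mov_support <- Reduce(`+`, lapply(moving$maps, function(m) m$data)) > 0.5
  fix_support <- Reduce(`+`, lapply(fixed$maps, function(m) m$data)) > 0.5
  stop_if(!any(mov_support & fix_support), "brain masks do not overlap")
  factors <- 2^((params$n_scales - 1):0)
  v <- NULL
  trace <- list()
  for (f in factors) {
    mov_s <- lapply(moving$maps, downsample_vol, factor = f)
    fix_s <- lapply(fixed$maps, downsample_vol, factor = f)
    grid_ref <- mov_s[[1]]
    d <- dim(grid_ref$data)
    vs <- voxel_size(grid_ref)
    if (is.null(v)) {
      comps <- lapply(1:3, function(j) array(0, d))
    } else {
      comps <- lapply(v$comps, function(cmp) {
        cv <- volume(cmp, affine = v$affine)
        resample(cv, grid_ref, order = 1L)$data
      })
    }
    v <- velocity_field(comps, grid_ref)
    fix_arr <- lapply(fix_s, function(m) m$data)
    ig <- index_grid(d)
    step <- params$step0_vox * mean(vs)
    warp_all <- function(vf) {
      phi <- exp_velocity(vf, order = 1L, step = 0.25)
      lapply(mov_s, function(m) warp_volume(m, phi, order = 1L)$data)
    }
    warped <- warp_all(v)
    ssd <- ssd_maps(warped, fix_arr)
    scale_trace <- ssd
    for (it in seq_len(params$iters_per_scale)) {
      force_c <- lapply(1:3, function(j) array(0, d))
      for (ci in seq_along(warped)) {
        diffc <- warped[[ci]] - fix_arr[[ci]]
        for (j in 1:3)
          force_c[[j]] <- force_c[[j]] + diffc * central_diff(warped[[ci]], j, vs[j])
      }
      sfw <- params$smooth_fwhm_vox / 2.355
      force_c <- lapply(force_c, smooth_array, sigma_vox = rep(sfw, 3))
      fmax <- sqrt(max(force_c[[1]]^2 + force_c[[2]]^2 + force_c[[3]]^2))
      if (fmax < 1e-12) break
      accepted <- FALSE
      for (bt in 1:5) {
        tau <- step / fmax
        v_try <- v
        v_try$comps <- lapply(1:3, function(j) v$comps[[j]] - tau * force_c[[j]])
        warped_try <- warp_all(v_try)
        ssd_try <- ssd_maps(warped_try, fix_arr)
        if (ssd_try < ssd) {
          v <- v_try; warped <- warped_try; ssd <- ssd_try
          step <- step * 1.2
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      scale_trace <- c(scale_trace, ssd)
      if (!accepted) break
    }
    trace[[length(trace) + 1L]] <- scale_trace
  }
  # return on the full-resolution grid
  if (!identical(v$dim, dim(ref$data))) {
    comps <- lapply(v$comps, function(cmp) {
      cv <- volume(cmp, affine = v$affine)
      resample(cv, ref, order = 1L)$data
    })
    v <- velocity_field(comps, ref)
  }
  attr(v, "ssd_trace") <- trace
  v
}

#' Build a group-average template from subject tissue maps
#'
#' Iterates register-to-template, averaging of the warped maps, and
#' recentring of the velocity fields to zero mean, starting from the plain
#' voxel-wise average.  `n_outer = 0` returns the plain average.
#'
#' @param subject_tpms list of [tpm_set]s on a shared grid
#' @param n_outer template refinement iterations
#' @param params registration parameters ([reg_params()])
#' @return list with `template` ([tpm_set]), `velocities` (list of
#'   [velocity_field]s) and `ssd_trace` (mean cross-subject SSD per
#'   iteration)
#' @export
build_template <- function(subject_tpms, n_outer = 3, params = reg_params()) {
  stop_if(length(subject_tpms) < 2, "need at least two subjects")
  classes <- names(subject_tpms[[1]]$maps)
  ref <- subject_tpms[[1]]$maps[[1]]
  avg_maps <- function(sets) {
    lapply(classes, function(cl) {
      m <- Reduce(`+`, lapply(sets, function(s) s$maps[[cl]]$data)) / length(sets)
      v <- vol_like(ref, m); v$space <- "group"; v
    })
  }
  template <- tpm_set(stats::setNames(avg_maps(subject_tpms), classes))
  velocities <- lapply(subject_tpms, function(s)
    velocity_field(lapply(1:3, function(j) array(0, dim(ref$data))), ref))
  ssd_trace <- mean_cross_ssd(subject_tpms, template, velocities)
  for (outer in seq_len(n_outer)) {
    velocities <- lapply(subject_tpms, register_pair, fixed = template,
                         params = params)
    mean_v <- lapply(1:3, function(j)
      Reduce(`+`, lapply(velocities, function(v) v$comps[[j]])) / length(velocities))
    velocities <- lapply(velocities, function(v) {
      v$comps <- lapply(1:3, function(j) v$comps[[j]] - mean_v[[j]])
      v
    })
    warped_sets <- mapply(function(s, v) {
      phi <- exp_velocity(v)
      tpm_set(stats::setNames(lapply(classes, function(cl) {
        w <- warp_volume(s$maps[[cl]], phi, order = 1L)
        w$space <- "group"; w
      }), classes))
    }, subject_tpms, velocities, SIMPLIFY = FALSE)
    template <- tpm_set(stats::setNames(avg_maps(warped_sets), classes))
    ssd_trace <- c(ssd_trace, mean_cross_ssd(subject_tpms, template, velocities))
  }
  list(template = template, velocities = velocities, ssd_trace = ssd_trace)
}

mean_cross_ssd <- function(subject_tpms, template, velocities) {
  classes <- names(template$maps)
  tot <- 0
  for (i in seq_along(subject_tpms)) {
    phi <- exp_velocity(velocities[[i]])
    w <- lapply(classes, function(cl)
      warp_volume(subject_tpms[[i]]$maps[[cl]], phi, order = 1L)$data)
    tot <- tot + ssd_maps(w, lapply(classes, function(cl) template$maps[[cl]]$data))
  }
  tot / length(subject_tpms)
}

#' Write a deformation field as 4-D NIfTI
#'
#' Stored as three volumes of target-space world coordinates (mm), i.e.
#' the mapped source position of every target voxel.
#'
#' @param phi a `deformation_field`
#' @param path output path (`.nii` / `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_deformation <- function(phi, path) {
  stopifnot(inherits(phi, "deformation_field"))
  ig <- index_grid(phi$dim)
  coords <- cbind(ig[, 1] + as.numeric(phi$disp[[1]]),
                  ig[, 2] + as.numeric(phi$disp[[2]]),
                  ig[, 3] + as.numeric(phi$disp[[3]]), 1)
  world <- coords %*% t(phi$affine)
  arr <- array(world[, 1:3], c(phi$dim, 3))
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(phi$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a deformation field from 4-D NIfTI
#'
#' Inverse of [write_deformation()]; world coordinates are converted back
#' to voxel displacements on the stored grid.
#'
#' @param path NIfTI path holding a 3-component coordinate field
#' @param space space tag for the target grid
#' @return a `deformation_field`
#' @export
read_deformation <- function(path, space = "group") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stop_if(length(d) != 4L || d[4] != 3L, "expected a 3-component 4-D NIfTI")
  aff <- unclass(RNifti::xform(img))
  dims <- d[1:3]
  world <- cbind(as.numeric(img[, , , 1]), as.numeric(img[, , , 2]),
                 as.numeric(img[, , , 3]), 1)
  vox <- world %*% t(solve(aff))
  ig <- index_grid(dims)
  disp <- lapply(1:3, function(j) array(vox[, j] - ig[, j], dims))
  deformation_field(disp, aff, dims, space)
}
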