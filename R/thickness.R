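#' Parameters for voxel-based cortical thickness
#'
#' `sampling_resolution_mm` is the isotropic grid on which the Laplace
#' equation is solved and streamlines are traced; `csf_smoothness_mm` and
#' `csf_thinness` control the reconstruction of thin, partial-volumed
#' sulcal CSF (the CSF probability map is smoothed by `csf_smoothness_mm`
#' and voxels whose smoothed CSF probability reaches `csf_thinness` are
#' forced to the CSF class before the argmax labelling); `n_dilations`
#' enlarges the solved grey-matter domain to stabilise the potential at
#' the tissue interfaces; thickness is capped at `max_thickness_mm`.
#'
#' @param sampling_resolution_mm sampling grid resolution (mm)
#' @param csf_smoothness_mm CSF smoothing kernel (mm)
#' @param csf_thinness threshold on the smoothed CSF probability
#' @param n_dilations dilation layers added to the GM Laplace domain
#' @param max_thickness_mm thickness cap (mm)
#' @return a `vbct_params` list
#' @export
vbct_params <- function(sampling_resolution_mm = 0.5, csf_smoothness_mm = 3,
                        csf_thinness = 0.65, n_dilations = 1,
                        max_thickness_mm = 10) {
  stop_if(sampling_resolution_mm <= 0, "sampling resolution must be > 0")
  stop_if(csf_thinness <= 0 || csf_thinness >= 1, "csf_thinness must be in (0, 1)")
  stop_if(n_dilations < 0, "n_dilations must be >= 0")
  structure(list(sampling_resolution_mm = sampling_resolution_mm,
                 csf_smoothness_mm = csf_smoothness_mm,
                 csf_thinness = csf_thinness, n_dilations = n_dilations,
                 max_thickness_mm = max_thickness_mm),
            class = "vbct_params")
}

#' Extract the grey-matter Laplace domain and its Dirichlet shells
#'
#' The repaired tissue maps are resampled to the sampling grid and
#' hard-labelled by argmax, with thin sulcal CSF reconstructed by
#' smoothing/thresholding the CSF map first.  The core GM set (argmax GM)
#' defines where thickness is measured; the solved domain is the core
#' dilated `n_dilations` times (restricted to tissue support), and the WM /
#' CSF Dirichlet shells are the argmax-WM / argmax-CSF voxels 6-adjacent to
#' that domain.
#'
#' @param tpms repaired [tpm_set] with classes `gm`, `wm`, `csf`
#' @param params a [vbct_params]
#' @return list of binary arrays `gm_core`, `gm_region`, `wm_boundary`,
#'   `csf_boundary` plus `grid` (a [volume] template of the sampling grid)
#' @export
extract_boundaries <- function(tpms, params = vbct_params()) {
  vs <- voxel_size(tpms$maps[[1]])
  s <- params$sampling_resolution_mm
  stop_if(s > min(vs) + 1e-9, "sampling resolution must not exceed the voxel size")
  d <- dim(tpms$maps[[1]]$data)
  factor <- s / vs
  nd <- as.integer(ceiling(d / factor))
  S <- diag(c(factor, 1))
  shift <- diag(4); shift[1:3, 4] <- (factor - 1) / 2
  taff <- tpms$maps[[1]]$affine %*% shift %*% S
  target <- list(dim = nd, affine = taff)
  gm <- resample(tpms$maps$gm, target, order = 1L)
  wm <- resample(tpms$maps$wm, target, order = 1L)
  csf <- resample(tpms$maps$csf, target, order = 1L)
  csf_s <- gaussian_smooth(csf, params$csf_smoothness_mm)
  g <- gm$data; w <- wm$data; c0 <- csf$data
  is_csf <- (c0 >= g & c0 >= w) | (csf_s$data >= params$csf_thinness)
  is_gm <- !is_csf & g >= w
  is_wm <- !is_csf & !is_gm
  support <- (g + w + c0) > 0.5
  core <- is_gm & support
  stop_if(!any(core), "empty grey-matter region")
  region <- core
  if (params$n_dilations > 0)
    region <- (dilate6(core, params$n_dilations) > 0) & support
  nb_region <- dilate6(region, 1L) > 0 & !region
  wm_b <- nb_region & is_wm
  csf_b <- nb_region & is_csf
  stop_if(!any(csf_b), "grey-matter region touches no CSF: topology error")
  stop_if(!any(wm_b), "grey-matter region touches no WM: topology error")
  list(gm_core = core, gm_region = region, wm_boundary = wm_b,
       csf_boundary = csf_b, grid = gm)
}

#' Solve the Laplace equation across the cortical ribbon
#'
#' Potential 0 on the WM shell, 1 on the CSF shell, relaxed by
#' successive over-relaxation until the largest update falls below `tol`.
#' Faces towards voxels outside the domain are treated as insulated.
#'
#' @param gm_region,wm_boundary,csf_boundary binary arrays from
#'   [extract_boundaries()] (or constructed directly)
#' @param grid optional [volume] template for the output
#' @param tol convergence tolerance on the max update (default 1e-5)
#' @param max_sweeps sweep limit (default 1e4)
#' @param omega over-relaxation factor
#' @return [volume] of the potential (0 outside the domain)
#' @export
solve_laplace <- function(gm_region, wm_boundary, csf_boundary, grid = NULL,
                          tol = 1e-5, max_sweeps = 10000L, omega = 1.9) {
  d <- dim(gm_region)
  stop_if(!any(wm_boundary) || !any(csf_boundary), "both boundary shells must be non-empty")
  code <- array(0L, d)
  code[gm_region != 0] <- 1L
  code[wm_boundary != 0] <- 2L
  code[csf_boundary != 0] <- 3L
  res <- cpp_laplace_sor(as.integer(code), d, omega, tol, as.integer(max_sweeps))
  stop_if(!res$converged,
          sprintf("Laplace relaxation did not converge in %d sweeps (max update %.2e)",
                  max_sweeps, res$max_delta))
  psi <- array(res$psi, d)
  if (is.null(grid)) volume(psi, voxel_size_mm = 1) else vol_like(grid, psi)
}

#' Streamline cortical thickness from the Laplace potential
#'
#' From each core GM voxel centre a streamline is traced along the
#' normalised potential gradient in both directions with RK4 steps of
#' `sampling_resolution / 5`, stopping where the interpolated core-GM
#' indicator crosses 0.5 (the half-voxel tissue interface); thickness is
#' the sum of both arc lengths, capped at `max_thickness_mm`.  Voxels with
#' a vanishing gradient inherit the nearest valid neighbour (their count
#' is recorded in the `n_fallback` attribute).
#'
#' @param psi potential [volume] from [solve_laplace()]
#' @param boundaries list from [extract_boundaries()]
#' @param params a [vbct_params]
#' @return thickness [volume] in mm on the sampling grid (0 outside GM)
#' @export
streamline_thickness <- function(psi, boundaries, params = vbct_params()) {
  d <- dim(psi$data)
  s <- params$sampling_resolution_mm
  gx <- central_diff(psi$data, 1, 1)
  gy <- central_diff(psi$data, 2, 1)
  gz <- central_diff(psi$data, 3, 1)
  core <- boundaries$gm_core * 1
  starts0 <- index_grid(d)[which(core > 0), , drop = FALSE]
  h <- 1 / 5                                   # RK4 step in sampling voxels
  max_len_vox <- params$max_thickness_mm / s
  len <- cpp_streamline_lengths(as.numeric(gx), as.numeric(gy), as.numeric(gz),
                                as.numeric(core), d, starts0, h, max_len_vox)
  thick <- array(0, d)
  thick[core > 0] <- len * s
  n_fb <- sum(is.na(thick))
  if (n_fb > 0) {
    # nearest-valid-neighbour fill for vanishing-gradient voxels
    for (pass in 1:10) {
      bad <- which(is.na(thick) & core > 0)
      if (length(bad) == 0) break
      filled <- thick; filled[is.na(filled)] <- 0
      valid <- (core > 0 & !is.na(thick)) * 1
      nb_sum <- Reduce(`+`, lapply(list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                                   function(o) shift3(filled, o[1], o[2], o[3])))
      nb_n <- Reduce(`+`, lapply(list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                                 function(o) shift3(valid, o[1], o[2], o[3])))
      fixable <- bad[nb_n[bad] > 0]
      thick[fixable] <- nb_sum[fixable] / nb_n[fixable]
    }
    thick[is.na(thick)] <- 0
  }
  thick <- pmin(thick, params$max_thickness_mm)
  out <- vol_like(boundaries$grid, thick)
  attr(out, "n_fallback") <- n_fb
  out
}

#' Voxel-based cortical thickness from repaired segmentations
#'
#' Composition of [extract_boundaries()], [solve_laplace()] and
#' [streamline_thickness()], with the result resampled back onto the
#' native grid (nearest neighbour) and restricted to argmax-GM voxels.
#' Deterministic: repeated runs give identical output.
#'
#' @param tpms repaired [tpm_set] (`gm`, `wm`, `csf`)
#' @param params a [vbct_params]
#' @return thickness [volume] in mm on the native grid
#' @export
vbct <- function(tpms, params = vbct_params()) {
  b <- extract_boundaries(tpms, params)
  psi <- solve_laplace(b$gm_region, b$wm_boundary, b$csf_boundary, grid = b$grid)
  thick <- streamline_thickness(psi, b, params)
  nat <- resample(thick, tpms$maps$gm, order = 0L)
  g <- tpms$maps$gm$data; w <- tpms$maps$wm$data; c0 <- tpms$maps$csf$data
  gm_native <- g >= w & g >= c0 & g > 0.1
  out <- vol_like(tpms$maps$gm, nat$data * gm_native)
  attr(out, "n_fallback") <- attr(thick, "n_fallback")
  out
}
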