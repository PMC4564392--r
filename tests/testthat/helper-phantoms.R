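# shared fixture builders: all synthetic, generated at test time

# one-hot truth tissue maps from a label volume (csf = background)
truth_tpms <- function(labels) {
  mk <- function(cls) vol_like_t(labels, (labels$data == cls) * 1)
  tpm_set(list(gm = mk(1), wm = mk(2), csf = mk(0)))
}

# vol_like is internal; tests go through the public surface where possible
vol_like_t <- function(v, data) {
  out <- volume(data, affine = v$affine, space = v$space)
  out
}

# small lesioned subject on a 2 mm grid, used across modules
small_lesioned_subject <- function(seed = 3, n_wmh = 8, n_li = 2,
                                   grid = 40, bias = 0) {
  sp <- phantom_spec(grid_shape = grid, voxel_size_mm = 2, wm_radius_mm = 25,
                     gm_thickness_mm = 5)
  lab <- make_labelmap(sp)
  les <- implant_lesions(lab, lesion_spec(n_wmh = n_wmh, n_li = n_li),
                         seed = seed)
  img <- render_intensities(les$labels, les$wmh, les$li,
                            intensity_model(bias_field_amplitude = bias),
                            li_core = les$li_core, seed = seed + 1)
  c(les, img, list(spec = sp))
}

# flat slab truth maps at 1 mm voxels with a given GM thickness
slab_tpms <- function(gm_thickness_mm = 4, grid = c(24, 24, 24), wm = 8) {
  sp <- phantom_spec(grid_shape = grid, voxel_size_mm = 1, wm_radius_mm = wm,
                     gm_thickness_mm = gm_thickness_mm, geometry = "flat_slab")
  truth_tpms(make_labelmap(sp))
}

# spherical shell truth maps at 1 mm voxels
shell_tpms <- function(wm_radius = 12, gm_thickness = 3, grid = 44) {
  sp <- phantom_spec(grid_shape = grid, voxel_size_mm = 1,
                     wm_radius_mm = wm_radius, gm_thickness_mm = gm_thickness)
  truth_tpms(make_labelmap(sp))
}

expect_same_array <- function(a, b, tol = 0) {
  expect_lte(max(abs(a - b)), tol)
}

# evaluate expr under a fixed seed without disturbing the global stream
with_seed_t <- function(seed, expr) {
  get("with_seed", envir = asNamespace("lesionmorph"))(seed, expr)
}
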