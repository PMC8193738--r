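# Shared fixtures, built once per test run and cached. Geometry is
# desk-scaled (smaller disc and bone stock than a bovine coccygeal
# specimen) while resolutions, marker layout, and the planted displacement
# and bulge distributions keep their study defaults.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (is.null(.fixtures[[name]])) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# full-resolution (82 um) phantom used for accuracy-critical checks
desk_config <- function(seed = 42, ...) {
  phantom_config(disc_radius = 5.5, disc_height = 9, bone_height = 2.5,
                 endcap_height = 2, margin = 1, seed = seed, ...)
}

# coarse (150 um) phantom for fast pipeline unit tests
coarse_config <- function(seed = 11, ...) {
  phantom_config(voxel_spacing = 0.15, disc_radius = 6, disc_height = 9,
                 bone_height = 2.5, endcap_height = 2, margin = 1,
                 seed = seed, ...)
}

# small marker-free specimen for FE work (moderate strains per step);
# defaults overridable through ...
fe_config <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(disc_radius = 5, disc_height = 6, bone_height = 2.5,
         endcap_height = 2, markers_per_line = 0L,
         step_displacements = rep(0.5, 4), seed = seed),
    list(...))
  do.call(phantom_config, args)
}

fx_coarse_phantom <- function() fx("coarse_phantom", function() {
  generate_phantom(coarse_config())
})

fx_coarse_deformed <- function() fx("coarse_deformed", function() {
  ph <- fx_coarse_phantom()
  def <- deform_phantom(ph, 1)
  tf <- register_rigid(def$ct, ph$ct, mode = "caudal")
  list(phantom = ph, def = def, tf = tf)
})

fx_fe_model <- function() fx("fe_model", function() {
  ph <- generate_phantom(fe_config(), render = FALSE)
  build_specimen_model(ph, "std_cyl", target_edge = 2.2)
})

fx_fe_record <- function() fx("fe_record", function() {
  model <- fx_fe_model()
  mats <- material_params(K_af = 800, K_np = 1500)
  fl <- forward_load_curve(model, mats, c(0.5, 1.0, 1.5))
  list(model = model, true_K = c(800, 1500),
       record = tibble::tibble(displacement_mm = fl$displacement_mm,
                               peak_load_N = fl$load_N))
})

# uniform single-material bar meshed from a label volume
fx_bar_model <- function(E = 100) {
  lab <- voxel_volume(array(2L, dim = c(10, 10, 20)), spacing = c(1, 1, 1),
                      origin = c(0.5, 0.5, 0.5))
  mesh <- mesh_specimen(lab, target_edge = 2.5)
  mesh$bone_E <- rep(E, nrow(mesh$elems))
  mesh <- assign_fibres(mesh)
  bc <- build_bcs(mesh, 0)
  structure(list(mesh = mesh, top_nodes = bc$top_nodes,
                 bottom_nodes = bc$bottom_nodes,
                 marker_map = tibble::tibble(marker_id = integer(),
                                             zone = character(),
                                             node = integer(),
                                             dist_mm = numeric()),
                 nucleus = NULL, geometry = NULL, nucleus_type = "std_cyl"),
            class = "specimen_model")
}

# random deformation gradients near identity with positive determinant
random_F <- function(n, scale = 0.08, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(3) + matrix(rnorm(9, 0, scale), 3, 3)
      if (det(F) > 0.3) return(F)
    }
  })
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

af_fibres <- function(angle_deg = 20) {
  a <- angle_deg * pi / 180
  cbind(c(cos(a), 0, sin(a)), c(cos(a), 0, -sin(a)))
}
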