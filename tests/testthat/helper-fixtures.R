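# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# homogeneous conducting bar, 5 x 5 x 40 voxels at 2 mm
bar_model <- function() fixture("bar", function() {
  n <- c(5L, 5L, 40L)
  lab <- array(match("gray", tesplan:::TISSUES), dim = n)
  m <- structure(list(dim = n, spacing = 2, center = (n / 2) * 2,
                      labels = lab, tissues = tesplan:::TISSUES,
                      sigma = NULL, table = NULL),
                 class = "voxel_head_model")
  assign_conductivities(m)
})

# coarse 4-shell planning stack: phantom, electrodes, cortex, LFM (8 mm)
coarse_stack <- function() fixture("coarse", function() {
  model <- build_shell_phantom(shell_spec(), 8)
  ctr <- model$center
  system <- assemble_fdm_system(model)
  electrodes <- place_geodesic_electrodes(model, 48)
  mesh <- icosphere(60, 3, center = ctr)
  parc <- parcellate_surface(mesh, 8)
  lfm <- lead_field_from_reciprocity(system, electrodes, parc, tol = 1e-8)
  list(model = model, ctr = ctr, system = system, electrodes = electrodes,
       mesh = mesh, parc = parc, lfm = lfm)
})

# homogeneous 4 mm sphere with electrodes and a coarse parcellation
homog_sphere_stack <- function() fixture("homog4", function() {
  model <- build_shell_phantom(shell_spec(radii = 92, tissues = "gray"), 4)
  ctr <- model$center
  system <- assemble_fdm_system(model)
  electrodes <- place_geodesic_electrodes(model, 16)
  mesh <- icosphere(60, 3, center = ctr)
  parc <- parcellate_surface(mesh, 8)
  lfm <- lead_field_from_reciprocity(system, electrodes, parc, tol = 1e-8)
  list(model = model, ctr = ctr, system = system, electrodes = electrodes,
       parc = parc, lfm = lfm)
})

# flat 2 x 2 cm square mesh (triangulated unit grid, 0.25 cm2 triangles)
flat_square_mesh <- function(side_mm = 20, step_mm = 2.5) {
  xs <- seq(0, side_mm, by = step_mm)
  nv <- length(xs)
  vtx <- as.matrix(expand.grid(x = xs, y = xs))
  vtx <- cbind(vtx, z = 0)
  idx <- function(i, j) (j - 1L) * nv + i
  faces <- NULL
  for (j in seq_len(nv - 1)) for (i in seq_len(nv - 1)) {
    faces <- rbind(faces,
                   c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  surface_mesh(vtx, faces, normals = matrix(rep(c(0, 0, 1), nrow(vtx)),
                                            ncol = 3, byrow = TRUE))
}

two_electrode_set <- function(model, dirs) {
  ctr <- model$center
  R <- max(shell_spec()$radii)
  out <- data.frame(id = sprintf("E%d", seq_len(nrow(dirs))),
                    x = ctr[1] + dirs[, 1], y = ctr[2] + dirs[, 2],
                    z = ctr[3] + dirs[, 3], area = 1)
  class(out) <- c("electrode_set", "data.frame")
  out
}
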