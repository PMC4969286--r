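test_that("flat square tiles into four ~1 cm2 patches", {
  mesh <- flat_square_mesh()
  parc <- parcellate_surface(mesh, 1.0)
  expect_equal(nrow(parc$patches), 4)
  expect_true(all(abs(parc$patches$area_cm2 - 1) <= 0.2))
  # flat patch normal equals the plane normal exactly
  for (p in parc$patches$id)
    expect_equal(as.numeric(patch_normal(parc, p)), c(0, 0, 1))
})

test_that("patch count follows area / target and areas are balanced", {
  m0 <- icosphere(1, 5)
  mesh <- icosphere(sqrt(120000 / sum(triangle_areas(m0))), 5)
  parc <- parcellate_surface(mesh, 1.0)
  expect_equal(nrow(parc$patches), 1200)
  expect_gte(mean(abs(parc$patches$area_cm2 - 1) < 0.5), 0.9)
})

test_that("parcellation partitions the mesh exactly", {
  set.seed(5)
  for (sub in c(3, 4)) {
    mesh <- wavy_gyrus_mesh(60, amplitude = 5, subdiv = sub)
    parc <- parcellate_surface(mesh, 6)
    expect_length(parc$membership, nrow(mesh$faces))
    expect_true(all(parc$membership %in% parc$patches$id))
    # areas sum to the mesh area
    expect_equal(sum(parc$patches$area_cm2) * 100, sum(triangle_areas(mesh)),
                 tolerance = 1e-9)
    # patches spatially connected
    adj <- tesplan:::face_adjacency(mesh)
    lab <- parc$membership
    g <- igraph::graph_from_edgelist(adj[lab[adj[, 1]] == lab[adj[, 2]], ],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, nrow(mesh$faces) - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    expect_equal(length(unique(comp)), nrow(parc$patches))
  }
})

test_that("degenerate triangles are cleaned with a warning", {
  mesh <- flat_square_mesh()
  faces <- rbind(mesh$faces, c(1, 1, 2))       # zero-area sliver
  m2 <- surface_mesh(mesh$vertices, faces)
  expect_warning(parc <- parcellate_surface(m2, 1.0), "degenerate")
  expect_equal(nrow(parc$patches), 4)
})

test_that("spherical cap patch normal points along the polar axis", {
  mesh <- icosphere(70, 4)
  cen <- triangle_centroids(mesh)
  cap <- which(cen[, 3] / sqrt(rowSums(cen^2)) > cos(30 * pi / 180))
  res <- tesplan:::patch_normal_raw(mesh, cap, triangle_areas(mesh))
  ang <- acos(min(1, sum(res$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
  expect_false(res$degenerate)
})

test_that("patch normals respond to sign and flag cancellation", {
  mesh <- icosphere(70, 3)
  parc <- parcellate_surface(mesh, 10)
  p1 <- parc$patches$id[1]
  n1 <- patch_normal(parc, p1)
  flipped <- parc
  flipped$mesh$normals <- -flipped$mesh$normals
  expect_equal(as.numeric(patch_normal(flipped, p1)), -as.numeric(n1))
  # opposing normals cancel -> degenerate flag, face-normal fallback
  canc <- parc
  canc$mesh$normals <- matrix(rep(c(1, 0, 0), nrow(mesh$vertices)),
                              ncol = 3, byrow = TRUE) *
    rep(c(1, -1), length.out = nrow(mesh$vertices))
  nd <- patch_normal(canc, p1)
  expect_true(isTRUE(attr(nd, "degenerate")) || abs(sum(nd^2) - 1) < 1e-9)
})

test_that("patch normals are invariant to mesh vertex reordering", {
  mesh <- icosphere(50, 3)
  parc <- parcellate_surface(mesh, 12)
  set.seed(21)
  perm <- sample(nrow(mesh$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mesh2 <- surface_mesh(mesh$vertices[perm, ],
                        matrix(inv[mesh$faces], ncol = 3),
                        normals = mesh$normals[perm, ])
  for (p in parc$patches$id[1:5]) {
    faces_p <- which(parc$membership == p)
    r1 <- tesplan:::patch_normal_raw(mesh, faces_p, triangle_areas(mesh))
    r2 <- tesplan:::patch_normal_raw(mesh2, faces_p, triangle_areas(mesh2))
    expect_equal(r1$normal, r2$normal, tolerance = 1e-12)
  }
})

test_that("nearest_patch minimizes centroid distance with lowest-id ties", {
  mesh <- icosphere(60, 3)
  parc <- parcellate_surface(mesh, 10)
  pts <- parc$patches
  # a centroid maps to its own patch
  expect_equal(nearest_patch(parc, as.numeric(pts[3, c("x", "y", "z")])),
               pts$id[3])
  # brute-force check on random points
  set.seed(11)
  for (i in 1:25) {
    q <- stats::runif(3, -70, 70)
    d <- (pts$x - q[1])^2 + (pts$y - q[2])^2 + (pts$z - q[3])^2
    expect_equal(nearest_patch(parc, q), pts$id[which.min(d)])
  }
  # exact tie breaks to the lower id
  mid <- (as.numeric(pts[1, c("x", "y", "z")]) +
          as.numeric(pts[2, c("x", "y", "z")])) / 2
  d <- (pts$x - mid[1])^2 + (pts$y - mid[2])^2 + (pts$z - mid[3])^2
  win <- which(abs(d - min(d)) < 1e-12)
  expect_equal(nearest_patch(parc, mid), pts$id[min(win)])
})

test_that("PLY round trip preserves the mesh", {
  mesh <- wavy_gyrus_mesh(50, amplitude = 4, subdiv = 3)
  f <- tempfile(fileext = ".ply")
  write_ply(mesh, f)
  back <- read_ply(f)
  expect_identical(back$faces, mesh$faces)
  expect_lt(max(abs(back$vertices - mesh$vertices)) / max(abs(mesh$vertices)),
            1e-9)
  expect_lt(max(abs(back$normals - mesh$normals)), 1e-6)
})
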