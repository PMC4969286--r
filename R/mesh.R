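#' Surface mesh constructor
#'
#' Triangle mesh with per-vertex outward normals. Normals, when not given,
#' are area-weighted averages of incident face normals, normalized to unit
#' length (outward provided the faces are consistently oriented
#' counter-clockwise seen from outside).
#'
#' @param vertices n x 3 matrix, mm.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @return object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) stop("face index out of range")
  if (is.null(normals)) normals <- vertex_normals(vertices, faces)
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "triangles, area", sprintf("%.2f", sum(triangle_areas(x)) / 100), "cm2\n")
  invisible(x)
}

# cross products of the two edge vectors of every triangle (rows)
face_cross <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Triangle areas (mm2)
#' @param mesh a \code{surface_mesh}.
#' @return numeric vector, one area per face.
#' @export
triangle_areas <- function(mesh) {
  cr <- face_cross(mesh$vertices, mesh$faces)
  0.5 * sqrt(rowSums(cr^2))
}

#' Triangle centroids (mm)
#' @param mesh a \code{surface_mesh}.
#' @return m x 3 matrix.
#' @export
triangle_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
     mesh$vertices[mesh$faces[, 3], ]) / 3
}

vertex_normals <- function(vertices, faces) {
  cr <- face_cross(vertices, faces)  # |cr| = 2 * area, direction = face normal
  nrm <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(cr[, c], faces[, k])
      nrm[as.integer(rownames(acc)), c] <- nrm[as.integer(rownames(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: near-uniform triangles,
#' consistently outward-oriented. 20 * 4^subdiv faces.
#'
#' @param radius sphere radius, mm.
#' @param subdiv number of 4-way subdivisions (0--6).
#' @param center sphere center, mm.
#' @return a [surface_mesh()].
#' @export
icosphere <- function(radius = 70, subdiv = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newv <- list()
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      if (!is.null(mids[[key]])) return(mids[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nrow(v) + length(newv)
      mids[[key]] <- id
      id
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

#' Wavy-gyrus sphere mesh
#'
#' Sphere with a sinusoidal radial perturbation producing gyrus/sulcus-like
#' undulations, including regions with opposing vertex normals; used to
#' exercise normal averaging on folded geometry.
#'
#' @param radius base radius, mm.
#' @param amplitude perturbation amplitude, mm.
#' @param waves angular frequency of the undulation.
#' @param subdiv icosphere subdivisions.
#' @param center center, mm.
#' @return a [surface_mesh()].
#' @export
wavy_gyrus_mesh <- function(radius = 70, amplitude = 6, waves = 6,
                            subdiv = 4, center = c(0, 0, 0)) {
  m <- icosphere(1, subdiv)
  d <- m$vertices
  th <- acos(pmin(1, pmax(-1, d[, 3])))
  ph <- atan2(d[, 2], d[, 1])
  r <- radius + amplitude * sin(waves * th) * cos(waves * ph)
  v <- d * r
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, m$faces)
}

#' Read / write ASCII PLY meshes
#'
#' Minimal ASCII PLY support: vertex x/y/z (plus optional nx/ny/nz) and
#' triangular faces.
#'
#' @param mesh a \code{surface_mesh}.
#' @param path file path.
#' @return \code{write_ply}: the path, invisibly; \code{read_ply}: a
#'   [surface_mesh()].
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment tesplan surface mesh (mm, corner-origin frame)",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  vd <- cbind(mesh$vertices, mesh$normals)
  writeLines(apply(format(vd, digits = 12, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdr_end <- match("end_header", lines)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  props <- sub("property float ", "", grep("^property float", hdr, value = TRUE))
  vl <- lines[hdr_end + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), nv, byrow = TRUE)
  colnames(vm) <- props[seq_len(ncol(vm))]
  fl <- lines[hdr_end + nv + seq_len(nf)]
  fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))), nf, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop("non-triangular face in PLY")
  nrm <- if (all(c("nx", "ny", "nz") %in% colnames(vm)))
    vm[, c("nx", "ny", "nz")] else NULL
  surface_mesh(vm[, c("x", "y", "z")], fm[, 2:4] + 1L, nrm)
}
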