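#' Parcel a cortical surface into approximately equal-area patches
#'
#' Splits a triangle mesh into \code{round(area / target_area)} spatially
#' connected patches of roughly \code{target_area} each, the unit used for
#' dipole targeting (~1 cm2 patches in a full-head model). Algorithm:
#' farthest-point sampling of k seed triangles, greedy assignment of every
#' triangle to its nearest seed (centroid distance), reconnection of any
#' stray components, and one boundary rebalancing pass that moves triangles
#' between adjacent patches when that reduces the total squared area
#' deviation from the target.
#'
#' Degenerate (zero-area) triangles are dropped with a warning before
#' parceling.
#'
#' @param mesh a [surface_mesh()].
#' @param target_area target patch area, cm2.
#' @return object of class \code{parcellation}: list with \code{patches}
#'   (data.frame: id, area_cm2, centroid x/y/z, normal nx/ny/nz, degenerate
#'   flag), \code{membership} (patch id per face), \code{mesh},
#'   \code{target_area}.
#' @export
parcellate_surface <- function(mesh, target_area = 1.0) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (target_area <= 0) stop("target_area must be > 0")
  areas <- triangle_areas(mesh)               # mm2
  degen <- areas <= 0
  if (any(degen)) {
    warning(sum(degen), " degenerate zero-area triangle(s) removed")
    mesh <- surface_mesh(mesh$vertices, mesh$faces[!degen, , drop = FALSE])
    areas <- areas[!degen]
  }
  total_cm2 <- sum(areas) / 100
  if (total_cm2 < target_area) stop("mesh area smaller than target patch area")
  k <- max(1L, as.integer(round(total_cm2 / target_area)))
  cen <- triangle_centroids(mesh)
  m <- nrow(cen)

  # farthest-point seed sampling (first seed: triangle farthest from the
  # mesh mean, an extremal point, so small k tilings land on the corners)
  seeds <- integer(k)
  mu <- colMeans(cen)
  d0 <- sqrt(colSums((t(cen) - mu)^2))
  seeds[1] <- which.max(d0)
  mind <- sqrt(colSums((t(cen) - cen[seeds[1], ])^2))
  if (k > 1) for (j in 2:k) {
    seeds[j] <- which.max(mind)
    dj <- sqrt(colSums((t(cen) - cen[seeds[j], ])^2))
    mind <- pmin(mind, dj)
  }

  # nearest-seed assignment, chunked to bound memory
  assign_near <- function(cen, seedpts) {
    lab <- integer(nrow(cen))
    step <- 20000L
    for (s in seq(1, nrow(cen), by = step)) {
      ii <- s:min(s + step - 1L, nrow(cen))
      d <- outer(rowSums(cen[ii, , drop = FALSE]^2), rowSums(seedpts^2), "+") -
        2 * cen[ii, , drop = FALSE] %*% t(seedpts)
      lab[ii] <- max.col(-d, ties.method = "first")
    }
    lab
  }
  lab <- assign_near(cen, cen[seeds, , drop = FALSE])

  adj <- face_adjacency(mesh)
  lab <- reconnect_components(lab, adj, k)
  lab <- rebalance_pass(lab, adj, areas, target_area * 100, k)
  lab <- reconnect_components(lab, adj, k)

  patches <- build_patch_table(mesh, lab, areas, k)
  structure(list(patches = patches, membership = lab, mesh = mesh,
                 target_area = target_area),
            class = "parcellation")
}

# edge-sharing face adjacency as an edge list (two columns of face ids)
face_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nrow(f)), 3)
  o <- order(key)
  key <- key[o]; fid <- fid[o]
  same <- which(key[-1] == key[-length(key)])
  cbind(fid[same], fid[same + 1])
}

# move each disconnected minor component of a patch to the neighbouring patch
# it touches most
reconnect_components <- function(lab, adj, k) {
  g <- igraph::graph_from_edgelist(adj[lab[adj[, 1]] == lab[adj[, 2]], ,
                                       drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lab) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  for (p in seq_len(k)) {
    faces_p <- which(lab == p)
    cc <- comp[faces_p]
    tb <- table(cc)
    if (length(tb) <= 1) next
    main <- as.integer(names(tb)[which.max(tb)])
    for (c0 in as.integer(names(tb))) {
      if (c0 == main) next
      stray <- faces_p[cc == c0]
      nb <- c(adj[adj[, 1] %in% stray, 2], adj[adj[, 2] %in% stray, 1])
      nb_lab <- lab[nb]
      nb_lab <- nb_lab[nb_lab != p]
      if (length(nb_lab)) lab[stray] <- as.integer(names(which.max(table(nb_lab))))
    }
  }
  lab
}

rebalance_pass <- function(lab, adj, areas, target_mm2, k, passes = 3L) {
  pa <- as.numeric(rowsum(areas, factor(lab, levels = seq_len(k))))
  for (p in seq_len(passes)) {
    boundary <- adj[lab[adj[, 1]] != lab[adj[, 2]], , drop = FALSE]
    cand <- rbind(boundary, boundary[, 2:1])
    moved <- 0L
    for (i in seq_len(nrow(cand))) {
      f <- cand[i, 1]; from <- lab[f]; to <- lab[cand[i, 2]]
      if (from == to) next
      a <- areas[f]
      old <- (pa[from] - target_mm2)^2 + (pa[to] - target_mm2)^2
      new <- (pa[from] - a - target_mm2)^2 + (pa[to] + a - target_mm2)^2
      if (new < old && pa[from] - a > 0) {
        lab[f] <- to
        pa[from] <- pa[from] - a
        pa[to] <- pa[to] + a
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
  }
  lab
}

build_patch_table <- function(mesh, lab, areas, k) {
  cen <- triangle_centroids(mesh)
  fl <- factor(lab, levels = seq_len(k))
  pa <- as.numeric(rowsum(areas, fl))
  cx <- as.numeric(rowsum(cen[, 1] * areas, fl)) / pa
  cy <- as.numeric(rowsum(cen[, 2] * areas, fl)) / pa
  cz <- as.numeric(rowsum(cen[, 3] * areas, fl)) / pa
  nrm <- matrix(NA_real_, k, 3)
  degen <- logical(k)
  for (p in seq_len(k)) {
    res <- patch_normal_raw(mesh, which(lab == p), areas)
    nrm[p, ] <- res$normal
    degen[p] <- res$degenerate
  }
  data.frame(id = seq_len(k), area_cm2 = pa / 100,
             x = cx, y = cy, z = cz,
             nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
             degenerate = degen)
}

patch_normal_raw <- function(mesh, faces_p, areas, area_weighted = TRUE) {
  if (!length(faces_p)) stop("patch is empty")
  f <- mesh$faces[faces_p, , drop = FALSE]
  a <- areas[faces_p]
  verts <- as.vector(t(f))
  w <- if (area_weighted) rep(a / 3, each = 3) else rep(1, length(verts))
  vn <- mesh$normals[verts, , drop = FALSE]
  m <- colSums(vn * w)
  len <- sqrt(sum(m^2))
  if (len < 1e-6 * sum(w)) {
    big <- faces_p[which.max(a)]
    cr <- face_cross(mesh$vertices, mesh$faces[big, , drop = FALSE])
    list(normal = cr / sqrt(sum(cr^2)), degenerate = TRUE)
  } else {
    list(normal = m / len, degenerate = FALSE)
  }
}

#' Averaged outward normal of a patch
#'
#' Area-weighted (default) or plain mean of the member vertex normals,
#' renormalized to unit length: the dipole orientation assigned to the
#' patch. Patches whose normals nearly cancel (opposing walls of a sulcus)
#' are flagged degenerate and fall back to the largest member triangle's
#' face normal.
#'
#' @param parc a [parcellate_surface()] result.
#' @param patch_id patch id.
#' @param area_weighted weight vertex normals by incident member area.
#' @return unit 3-vector with attribute \code{degenerate}.
#' @export
patch_normal <- function(parc, patch_id, area_weighted = TRUE) {
  stopifnot(inherits(parc, "parcellation"))
  faces_p <- which(parc$membership == patch_id)
  res <- patch_normal_raw(parc$mesh, faces_p, triangle_areas(parc$mesh),
                          area_weighted)
  structure(as.numeric(res$normal), degenerate = res$degenerate)
}

#' Patch nearest to a point
#'
#' @param parc a [parcellate_surface()] result.
#' @param point length-3 position, mm (e.g. a TMS hotspot coordinate).
#' @return patch id with minimum centroid distance; ties break to the
#'   lowest id.
#' @export
nearest_patch <- function(parc, point) {
  stopifnot(inherits(parc, "parcellation"))
  p <- parc$patches
  d <- (p$x - point[1])^2 + (p$y - point[2])^2 + (p$z - point[3])^2
  p$id[which.min(d)]   # which.min returns the first (lowest id) on ties
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", nrow(x$patches), "patches, target",
      x$target_area, "cm2; areas",
      sprintf("%.2f-%.2f cm2", min(x$patches$area_cm2), max(x$patches$area_cm2)),
      "\n")
  invisible(x)
}

#' Write a parcellation to JSON (+ per-face CSV)
#' @param parc a \code{parcellation}.
#' @param path JSON output path; a sibling \code{*_faces.csv} is written too.
#' @return \code{path}, invisibly.
#' @export
write_parcellation_json <- function(parc, path) {
  obj <- list(target_area_cm2 = parc$target_area,
              patches = parc$patches,
              membership = parc$membership)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  csv <- sub("\\.json$", "_faces.csv", path)
  utils::write.csv(data.frame(face = seq_along(parc$membership),
                              patch = parc$membership), csv, row.names = FALSE)
  invisible(path)
}
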