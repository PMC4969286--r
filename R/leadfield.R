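#' Lead-field matrix by the reciprocity construction
#'
#' Builds the electrodes x patches lead-field matrix: entry (e, p) is the
#' average-referenced voltage at electrode e produced by a unit current
#' dipole (1 A m) at the centroid of cortical patch p, oriented along the
#' patch's averaged outward normal. By reciprocity this equals the
#' directional derivative of the potential at the patch centroid when unit
#' current is driven through electrode e (against a reference electrode),
#' so the whole matrix costs one forward solve per electrode instead of
#' one per patch. The gradient is evaluated by central differences of the
#' trilinearly interpolated potential, and columns are re-referenced to
#' zero mean over electrodes.
#'
#' @param system an [assemble_fdm_system()] result.
#' @param electrodes an \code{electrode_set} (>= 2 rows).
#' @param parcellation a [parcellate_surface()] result; patch centroids
#'   must fall in conducting (normally gray-matter) voxels.
#' @param tol CG relative tolerance per solve.
#' @param keep_fields retain the per-electrode potential fields (needed by
#'   [target_dose_basis()] and fast montage evaluation).
#' @return object of class \code{lead_field}: \code{matrix}
#'   (electrodes x patches, V per A m), \code{electrode_ids},
#'   \code{patch_ids}, \code{reference = "average"}, and optionally
#'   \code{fields} (list of per-electrode potentials vs the reference
#'   electrode).
#' @export
lead_field_from_reciprocity <- function(system, electrodes, parcellation,
                                        tol = 1e-8, keep_fields = TRUE) {
  stopifnot(inherits(system, "fdm_system"), inherits(parcellation, "parcellation"))
  ne <- nrow(electrodes)
  if (ne < 2) stop("need at least 2 electrodes")
  pts <- as.matrix(parcellation$patches[, c("x", "y", "z")])
  nrm <- as.matrix(parcellation$patches[, c("nx", "ny", "nz")])
  # centroids must be in (or within one voxel of) conducting tissue
  gidx <- round(pts / system$model$spacing + 0.5)
  n <- system$model$dim
  inside <- gidx >= 1 & sweep(gidx, 2, n, "<=")
  lin <- gidx[, 1] + n[1] * (gidx[, 2] - 1) + n[1] * n[2] * (gidx[, 3] - 1)
  bad <- !apply(inside, 1, all)
  bad[!bad] <- system$model$sigma[lin[!bad]] <= 0
  if (any(bad))
    stop("patch centroid in non-conducting voxel: patch ",
         paste(parcellation$patches$id[bad], collapse = ", "))

  en <- electrode_nodes(system, electrodes)
  ref <- ne
  L <- matrix(0, ne, nrow(pts))
  fields <- if (keep_fields) vector("list", ne) else NULL
  for (e in seq_len(ne - 1)) {
    s <- numeric(length(system$nodes))
    s[en[e]] <- s[en[e]] + 1
    s[en[ref]] <- s[en[ref]] - 1
    phi <- solve_nodal(system, s, tol = tol)
    fld <- as_potential_field(system, phi)
    if (keep_fields) fields[[e]] <- fld
    g <- grad_phi(fld, pts)
    L[e, ] <- rowSums(g * nrm)           # V/m per 1 A = V per A m dipole
  }
  L <- sweep(L, 2, colMeans(L))          # average reference over electrodes
  structure(list(matrix = L,
                 electrode_ids = electrodes$id,
                 patch_ids = parcellation$patches$id,
                 reference = "average",
                 ref_electrode = ref,
                 fields = fields,
                 electrodes = electrodes,
                 parcellation = parcellation,
                 system = system),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("lead field:", nrow(x$matrix), "electrodes x", ncol(x$matrix),
      "patches (", x$reference, "reference )\n")
  invisible(x)
}

#' Predicted scalp voltages for a dipole via an explicit dipole solve
#'
#' Direct route used to cross-check reciprocity: represents the dipole as
#' two opposite monopoles one grid spacing apart along the orientation,
#' solves the forward problem once, and reads the (average-referenced)
#' potential at the electrode nodes, scaled to unit moment.
#'
#' @param system an \code{fdm_system}.
#' @param electrodes an \code{electrode_set}.
#' @param position dipole location, mm.
#' @param orientation unit 3-vector.
#' @param tol CG tolerance.
#' @return voltages at electrodes (V per A m), average reference.
#' @export
dipole_scalp_voltages <- function(system, electrodes, position, orientation,
                                  tol = 1e-8) {
  h <- system$model$spacing
  orientation <- orientation / sqrt(sum(orientation^2))
  en <- electrode_nodes(system, electrodes)
  # anchor at the conducting voxel nearest the requested position; an
  # arbitrary orientation is the linear combination of three axis-aligned
  # monopole pairs (+/- one voxel from the anchor), which keeps every
  # monopole exactly on a grid node
  pos <- voxel_centers(system$model, system$nodes)
  anchor <- pos[which.min(colSums((t(pos) - position)^2)), ]
  v <- numeric(nrow(electrodes))
  for (k in 1:3) {
    if (orientation[k] == 0) next
    off <- c(0, 0, 0); off[k] <- h
    fld <- solve_point_sources(system, rbind(anchor + off, anchor - off),
                               c(1, -1), tol = tol)
    v <- v + orientation[k] * fld$values[en] / (2 * h / 1000)
  }
  v - mean(v)
}

#' Lead-field entries at arbitrary dipole locations
#'
#' Evaluates the reciprocity lead field for dipoles at given positions and
#' orientations (not necessarily patch centroids), from the stored
#' per-electrode solves. Returns voltages at the anchor voxel of the
#' dipole oracle when \code{snap = TRUE}, which makes entries directly
#' comparable with [dipole_scalp_voltages()] at the same grid location.
#'
#' @param lfm a \code{lead_field} built with \code{keep_fields = TRUE}.
#' @param positions k x 3 matrix, mm.
#' @param orientations k x 3 matrix of unit vectors.
#' @param snap evaluate at the conducting voxel center nearest each
#'   position (the dipole oracle's anchor) instead of the exact position.
#' @return electrodes x k matrix, V per A m, average reference.
#' @export
lead_field_entries <- function(lfm, positions, orientations, snap = FALSE) {
  stopifnot(inherits(lfm, "lead_field"))
  if (is.null(lfm$fields)) stop("lead field was built with keep_fields = FALSE")
  positions <- matrix(positions, ncol = 3)
  orientations <- matrix(orientations, ncol = 3)
  if (snap) {
    pos <- voxel_centers(lfm$system$model, lfm$system$nodes)
    for (i in seq_len(nrow(positions)))
      positions[i, ] <- pos[which.min(colSums((t(pos) - positions[i, ])^2)), ]
  }
  ne <- length(lfm$electrode_ids)
  L <- matrix(0, ne, nrow(positions))
  for (e in seq_len(ne - 1)) {
    g <- grad_phi(lfm$fields[[e]], positions)
    L[e, ] <- rowSums(g * orientations)
  }
  sweep(L, 2, colMeans(L))
}

#' Per-electrode target dose basis
#'
#' For a target patch, the signed normal current density (anodal direction,
#' scalp to cortex) at the patch centroid produced by a unit current (1 A)
#' driven through each electrode against the lead field's reference
#' electrode. By linearity, any zero-sum montage's target dose is the dot
#' product of this basis with the montage currents, which makes Monte-Carlo
#' montage comparisons cheap.
#'
#' @param lfm a [lead_field_from_reciprocity()] result built with
#'   \code{keep_fields = TRUE}.
#' @param patch_id target patch.
#' @return numeric vector, A/m2 per ampere, one entry per electrode.
#' @export
target_dose_basis <- function(lfm, patch_id) {
  stopifnot(inherits(lfm, "lead_field"))
  if (is.null(lfm$fields)) stop("lead field was built with keep_fields = FALSE")
  p <- match(patch_id, lfm$patch_ids)
  if (is.na(p)) stop("unknown patch id: ", patch_id)
  pt <- as.numeric(lfm$parcellation$patches[p, c("x", "y", "z")])
  nrm <- as.numeric(lfm$parcellation$patches[p, c("nx", "ny", "nz")])
  sig <- sigma_at(lfm$system$model, pt)
  ne <- length(lfm$electrode_ids)
  basis <- numeric(ne)
  for (e in seq_len(ne - 1)) {
    g <- grad_phi(lfm$fields[[e]], pt)
    # anodal-positive convention: dose = -J . n_out = +sigma * (grad phi . n)
    basis[e] <- sig * sum(g * nrm)
  }
  basis
}

sigma_at <- function(model, point) {
  gidx <- pmin(pmax(round(point / model$spacing + 0.5), 1), model$dim)
  model$sigma[matrix(gidx, ncol = 3)]
}

#' Write / read a lead-field matrix (plain-text store)
#'
#' The matrix goes to CSV (electrodes x patches, row names = electrode
#' ids); ids and the reference tag go to a JSON sidecar.
#'
#' @param lfm a \code{lead_field}.
#' @param path CSV path; the sidecar is \code{<path>.json}.
#' @return \code{path} / a \code{lead_field} (without solver fields).
#' @export
write_lead_field <- function(lfm, path) {
  m <- lfm$matrix
  rownames(m) <- lfm$electrode_ids
  colnames(m) <- paste0("P", lfm$patch_ids)
  utils::write.csv(format(m, digits = 17, trim = TRUE), path)
  jsonlite::write_json(list(electrode_ids = lfm$electrode_ids,
                            patch_ids = lfm$patch_ids,
                            reference = lfm$reference),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  structure(list(matrix = m, electrode_ids = meta$electrode_ids,
                 patch_ids = meta$patch_ids, reference = meta$reference,
                 fields = NULL),
            class = "lead_field")
}
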