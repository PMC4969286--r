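#' Tissue conductivity table
#'
#' Literature conductivities (S/m) for the seven tissue classes used by the
#' volume-conductor model: eyeball 1.5, scalp 0.44, skull 0.018, CSF 1.79,
#' gray matter 0.25, white matter 0.35, air 0. Air must be exactly zero;
#' every other value must be non-negative.
#'
#' @param values named numeric vector overriding individual defaults.
#' @return named numeric vector of class \code{conductivity_table} covering
#'   all seven tissue labels.
#' @examples
#' conductivity_table()[["scalp"]]   # 0.44
#' @export
conductivity_table <- function(values = NULL) {
  tab <- c(eyeball = 1.5, scalp = 0.44, skull = 0.018, csf = 1.79,
           gray = 0.25, white = 0.35, air = 0)
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(tab))
    if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
    tab[names(values)] <- values
  }
  if (any(tab < 0)) stop("conductivities must be >= 0")
  if (tab[["air"]] != 0) stop("air conductivity must be exactly 0")
  structure(tab, class = c("conductivity_table", "numeric"))
}

TISSUES <- c("air", "scalp", "skull", "csf", "gray", "white", "eyeball")

#' Concentric-shell specification
#'
#' Ordered shells (innermost first) with strictly increasing outer radii.
#' The default 4-shell head uses gray matter to 78 mm, CSF to 80 mm, skull
#' to 85 mm and scalp to 92 mm, a common adult-head scale.
#'
#' @param radii outer radius of each shell, mm, strictly increasing.
#' @param tissues tissue label per shell (see [conductivity_table()]).
#' @param center sphere center, mm; \code{NULL} places it at the grid center
#'   when the phantom is built.
#' @return object of class \code{shell_spec}.
#' @export
shell_spec <- function(radii = c(78, 80, 85, 92),
                       tissues = c("gray", "csf", "skull", "scalp"),
                       center = NULL) {
  if (length(radii) != length(tissues)) stop("radii and tissues differ in length")
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("shell radii must be positive and strictly increasing")
  bad <- setdiff(tissues, TISSUES)
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (!tissues[1] %in% c("gray", "white"))
    stop("innermost shell must be a brain tissue (gray or white)")
  structure(list(radii = radii, tissues = tissues, center = center),
            class = "shell_spec")
}

#' Build a voxel head phantom from concentric shells
#'
#' Voxelizes a [shell_spec()] on a regular isotropic grid. Each voxel is
#' labeled by the innermost shell whose radius its center falls within
#' (a voxel-center point-in-region test, no partial-volume handling);
#' voxels outside the outermost radius are air. The grid is sized so the
#' outer shell plus one air layer fits, with an odd voxel count per axis so
#' the sphere center coincides with a voxel center.
#'
#' @param spec a [shell_spec()].
#' @param spacing isotropic voxel spacing, mm.
#' @param table conductivity table used to fill the conductivity volume.
#' @return object of class \code{voxel_head_model}: list with \code{dim},
#'   \code{spacing} (mm), \code{center} (mm), integer \code{labels} array
#'   (values index \code{tissues}), \code{tissues}, numeric \code{sigma}
#'   array (S/m), and the \code{table} used.
#' @export
build_shell_phantom <- function(spec, spacing, table = conductivity_table()) {
  stopifnot(inherits(spec, "shell_spec"))
  if (spacing <= 0) stop("spacing must be > 0")
  rmax <- max(spec$radii)
  half <- ceiling((rmax + spacing) / spacing)  # voxels per half-axis
  n <- 2L * half + 1L
  # voxel centers at (i - 0.5) * spacing, i = 1..n; center voxel index half+1
  ctr <- (half + 0.5) * spacing
  center <- if (is.null(spec$center)) rep(ctr, 3) else spec$center
  ax <- (seq_len(n) - 0.5) * spacing
  dx2 <- (ax - center[1])^2
  dy2 <- (ax - center[2])^2
  dz2 <- (ax - center[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  lab <- array(1L, dim = c(n, n, n))  # air
  for (k in rev(seq_along(spec$radii))) {   # outermost first, inner overwrite
    code <- match(spec$tissues[k], TISSUES)
    lab[r <= spec$radii[k]] <- code
  }
  model <- structure(list(dim = c(n, n, n), spacing = spacing, center = center,
                          labels = lab, tissues = TISSUES,
                          sigma = NULL, table = NULL),
                     class = "voxel_head_model")
  assign_conductivities(model, table)
}

#' Map tissue labels to conductivities
#'
#' Fills (or refreshes) the per-voxel conductivity volume by looking each
#' voxel's tissue label up in a conductivity table.
#'
#' @param model a \code{voxel_head_model}.
#' @param table a [conductivity_table()].
#' @return the model with \code{sigma} set to \code{table[label]} voxelwise.
#' @export
assign_conductivities <- function(model, table = conductivity_table()) {
  stopifnot(inherits(model, "voxel_head_model"))
  used <- model$tissues[sort(unique(as.integer(model$labels)))]
  missing <- setdiff(used, names(table))
  if (length(missing))
    stop("conductivity table lacks label(s): ", paste(missing, collapse = ", "))
  sig <- array(unname(table[model$tissues[model$labels]]), dim = model$dim)
  model$sigma <- sig
  model$table <- table
  model
}

#' @export
print.voxel_head_model <- function(x, ...) {
  cat("voxel head model:", paste(x$dim, collapse = " x "),
      "voxels @", x$spacing, "mm\n")
  tb <- table(factor(x$tissues[x$labels], levels = x$tissues))
  for (t in names(tb)) if (tb[[t]] > 0)
    cat(sprintf("  %-8s %8d voxels\n", t, tb[[t]]))
  invisible(x)
}

#' Voxel-center coordinates (mm) for a model
#' @param model a \code{voxel_head_model}.
#' @param which linear voxel indices; all voxels when NULL.
#' @return matrix with columns x, y, z.
#' @keywords internal
voxel_centers <- function(model, which = NULL) {
  n <- model$dim
  if (is.null(which)) which <- seq_len(prod(n))
  idx <- arrayInd(which, n)
  (idx - 0.5) * model$spacing
}

#' Outer scalp-surface voxels
#'
#' Linear indices of scalp voxels that touch an air voxel across a face:
#' the discrete scalp surface electrodes snap to.
#' @keywords internal
scalp_surface_voxels <- function(model, tissue = "scalp") {
  lab <- model$labels
  n <- model$dim
  scalp <- if (identical(tissue, "any")) which(model$sigma > 0)
           else which(lab == match(tissue, TISSUES))
  if (!length(scalp)) stop("model has no ", tissue, " voxels")
  air <- model$sigma == 0
  idx <- arrayInd(scalp, n)
  touches <- rep(FALSE, length(scalp))
  for (k in 1:3) for (s in c(-1L, 1L)) {
    nb <- idx
    nb[, k] <- nb[, k] + s
    ok <- nb[, k] >= 1L & nb[, k] <= n[k]
    lin <- nb[ok, 1] + n[1] * (nb[ok, 2] - 1L) + n[1] * n[2] * (nb[ok, 3] - 1L)
    touches[ok] <- touches[ok] | air[lin]
    touches[!ok] <- TRUE               # grid boundary counts as outside
  }
  scalp[touches]
}

#' Place a geodesic electrode array on the scalp
#'
#' Samples approximately evenly spaced directions on a spherical cap
#' (Fibonacci spiral) centered on +z and snaps each direction to the
#' best-aligned outer scalp-surface voxel, emulating a dense geodesic
#' sensor net. The cap extends to a configurable polar angle (default
#' 120 degrees) so electrodes stay on the upper head, as with a scalp net.
#'
#' @param model a \code{voxel_head_model} with scalp voxels.
#' @param n_electrodes number of electrodes (>= 2).
#' @param polar_cutoff_deg maximum polar angle from +z, degrees.
#' @param area contact area per electrode, cm2.
#' @return an \code{electrode_set}: data.frame with columns
#'   \code{id, x, y, z, area} (mm, cm2).
#' @export
place_geodesic_electrodes <- function(model, n_electrodes,
                                      polar_cutoff_deg = 120, area = 1.0) {
  stopifnot(inherits(model, "voxel_head_model"))
  if (n_electrodes < 2) stop("need at least 2 electrodes")
  has_scalp <- any(model$labels == match("scalp", TISSUES))
  surf <- scalp_surface_voxels(model, if (has_scalp) "scalp" else "any")
  pos <- voxel_centers(model, surf)
  rel <- sweep(pos, 2, model$center)
  rn <- sqrt(rowSums(rel^2))
  dirs <- rel / rn
  zmin <- cos(polar_cutoff_deg * pi / 180)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_electrodes)
  z <- 1 - (i - 0.5) / n_electrodes * (1 - zmin)
  th <- golden * (i - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  want <- cbind(cos(th) * s, sin(th) * s, z)
  pick <- integer(n_electrodes)
  for (j in i) pick[j] <- which.max(dirs %*% want[j, ])
  if (anyDuplicated(pick))
    stop("n_electrodes exceeds available scalp surface resolution ",
         "(two spiral points snapped to the same voxel)")
  out <- data.frame(id = sprintf("E%03d", i),
                    x = pos[pick, 1], y = pos[pick, 2], z = pos[pick, 3],
                    area = area, stringsAsFactors = FALSE)
  class(out) <- c("electrode_set", "data.frame")
  out
}

#' Write / read label or conductivity volumes as NIfTI
#'
#' @param model a \code{voxel_head_model}.
#' @param path output file (.nii / .nii.gz).
#' @param what \code{"labels"} or \code{"sigma"}.
#' @return \code{path}, invisibly.
#' @export
write_phantom_nifti <- function(model, path, what = c("labels", "sigma")) {
  what <- match.arg(what)
  vol <- if (what == "labels") model$labels else model$sigma
  attr(vol, "pixdim") <- rep(model$spacing, 3)
  img <- RNifti::asNifti(vol, datatype = if (what == "labels") "int16" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @param spacing voxel spacing override; taken from the NIfTI header when NULL.
#' @param table conductivity table for relabeling.
#' @export
read_phantom_nifti <- function(path, spacing = NULL, table = conductivity_table()) {
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(round(as.array(img))), dim = dim(img))
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)[1]
  n <- dim(lab)
  model <- structure(list(dim = n, spacing = spacing,
                          center = (n / 2) * spacing,
                          labels = lab, tissues = TISSUES,
                          sigma = NULL, table = NULL),
                     class = "voxel_head_model")
  assign_conductivities(model, table)
}
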