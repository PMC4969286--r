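#' Assemble the finite-difference current-flow system
#'
#' Discretizes the quasi-static current-flow equation div(sigma grad phi) = -s
#' on the voxel grid with a 7-point stencil. The conductance across each
#' voxel face is the harmonic mean of the two adjacent voxel conductivities
#' times the face geometry factor (h in meters for an isotropic grid), which
#' makes the discrete flux continuous across tissue boundaries. Air voxels
#' carry no unknowns, so every conductor--air face naturally imposes a
#' zero-flux (Neumann) boundary. The resulting operator is symmetric
#' positive semidefinite with a one-dimensional null space (constant
#' potential); solves fix one reference node and re-reference afterwards.
#'
#' @param model a \code{voxel_head_model} with conductivities assigned.
#' @return object of class \code{fdm_system}: \code{A} (sparse conductance
#'   Laplacian over conducting voxels, siemens), \code{nodes} (linear voxel
#'   index per unknown), \code{node_of_voxel} (inverse map, 0 for air),
#'   \code{model}.
#' @export
assemble_fdm_system <- function(model) {
  stopifnot(inherits(model, "voxel_head_model"), !is.null(model$sigma))
  n <- model$dim
  sig <- model$sigma
  cond <- which(sig > 0)
  if (!length(cond)) stop("model has no conducting voxel")
  node_of <- integer(prod(n))
  node_of[cond] <- seq_along(cond)
  h_m <- model$spacing / 1000

  ii <- jj <- integer(0)
  gg <- numeric(0)
  stride <- c(1L, n[1], n[1] * n[2])
  idx <- arrayInd(cond, n)
  for (k in 1:3) {
    ok <- idx[, k] < n[k]
    a <- cond[ok]
    b <- a + stride[k]
    keep <- sig[b] > 0
    a <- a[keep]; b <- b[keep]
    g <- 2 * sig[a] * sig[b] / (sig[a] + sig[b]) * h_m
    ii <- c(ii, node_of[a]); jj <- c(jj, node_of[b]); gg <- c(gg, g)
  }
  nn <- length(cond)
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(gg, gg),
                            dims = c(nn, nn))
  A <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W

  g <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  if (igraph::vcount(g) < nn) g <- igraph::add_vertices(g, nn - igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("conducting region is disconnected; component sizes: ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))

  structure(list(A = A, nodes = cond, node_of_voxel = node_of, model = model),
            class = "fdm_system")
}

#' @export
print.fdm_system <- function(x, ...) {
  cat("FDM system:", length(x$nodes), "conducting voxels,",
      Matrix::nnzero(x$A), "nonzeros\n")
  invisible(x)
}

# Jacobi-preconditioned conjugate gradients on the SPD reduced system.
pcg_solve <- function(A, b, tol = 1e-8, maxit = 20000L) {
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iters = 0L, relres = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres <= tol) return(list(x = x, iters = it, relres = relres))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning("PCG did not reach tolerance ", tol, " (relres ", signif(relres, 3), ")")
  list(x = x, iters = maxit, relres = relres)
}

# Solve A phi = s (s in amperes per node) with node `ground` fixed at 0,
# then shift phi to zero mean over conducting voxels.
solve_nodal <- function(system, s, tol = 1e-8, ground = NULL) {
  nn <- length(system$nodes)
  if (is.null(ground)) ground <- nn   # a corner-ish scalp voxel
  if (abs(sum(s)) > 1e-9 * max(abs(s), 1e-300))
    stop("source currents must sum to zero (singular Neumann system)")
  keep <- setdiff(seq_len(nn), ground)
  if (is.null(system$red) || !identical(system$ground, ground)) {
    Ared <- system$A[keep, keep]
  } else Ared <- system$red
  sol <- pcg_solve(Ared, s[keep], tol = tol)
  phi <- numeric(nn)
  phi[keep] <- sol$x
  phi <- phi - mean(phi)
  attr(phi, "iters") <- sol$iters
  attr(phi, "relres") <- sol$relres
  phi
}

#' Map electrode positions to conducting grid nodes
#'
#' Each electrode becomes the nearest scalp-surface voxel (point-electrode
#' model; the contact area is used only for current-density reporting).
#' @keywords internal
electrode_nodes <- function(system, electrodes) {
  has_scalp <- any(system$model$labels == match("scalp", TISSUES))
  surf <- scalp_surface_voxels(system$model, if (has_scalp) "scalp" else "any")
  pos <- voxel_centers(system$model, surf)
  sapply(seq_len(nrow(electrodes)), function(i) {
    p <- c(electrodes$x[i], electrodes$y[i], electrodes$z[i])
    v <- surf[which.min(colSums((t(pos) - p)^2))]
    system$node_of_voxel[v]
  })
}

#' Solve a scalp current-injection pattern
#'
#' Forward solve for a zero-sum set of electrode currents; returns the
#' potential on the voxel grid in average reference (zero mean over
#' conducting voxels).
#'
#' @param system an [assemble_fdm_system()] result.
#' @param electrodes an \code{electrode_set}.
#' @param pattern per-electrode current, microamperes; must sum to zero
#'   (relative to the largest magnitude) or the singular system has no
#'   solution.
#' @param tol relative residual tolerance of the conjugate-gradient solve.
#' @return object of class \code{potential_field}: \code{phi} array (volts,
#'   NA in air), \code{values} (per conducting node), \code{reference}
#'   ("average"), solver diagnostics.
#' @export
solve_injection <- function(system, electrodes, pattern, tol = 1e-8) {
  stopifnot(inherits(system, "fdm_system"))
  if (length(pattern) != nrow(electrodes))
    stop("pattern length must match electrode count")
  mx <- max(abs(pattern))
  if (mx > 0 && abs(sum(pattern)) > 1e-9 * mx)
    stop("injection pattern must sum to zero")
  s <- numeric(length(system$nodes))
  en <- electrode_nodes(system, electrodes)
  for (i in seq_along(pattern)) s[en[i]] <- s[en[i]] + pattern[i] * 1e-6  # uA -> A
  phi <- solve_nodal(system, s, tol = tol)
  as_potential_field(system, phi)
}

as_potential_field <- function(system, phi) {
  vol <- array(NA_real_, dim = system$model$dim)
  vol[system$nodes] <- phi
  structure(list(phi = vol, values = as.numeric(phi), reference = "average",
                 iters = attr(phi, "iters"), relres = attr(phi, "relres"),
                 model = system$model),
            class = "potential_field")
}

#' Solve a point-source configuration (dipole oracle)
#'
#' Places signed point currents at the conducting voxels nearest the given
#' positions and solves. Used to represent a dipole as two opposite
#' monopoles a grid spacing apart along the patch normal.
#'
#' @param system an \code{fdm_system}.
#' @param positions k x 3 matrix, mm.
#' @param currents k signed currents, amperes; must sum to zero.
#' @param tol CG tolerance.
#' @return a \code{potential_field}.
#' @export
solve_point_sources <- function(system, positions, currents, tol = 1e-8) {
  stopifnot(inherits(system, "fdm_system"))
  positions <- matrix(positions, ncol = 3)
  if (abs(sum(currents)) > 1e-9 * max(abs(currents)))
    stop("point-source currents must sum to zero")
  pos <- voxel_centers(system$model, system$nodes)
  s <- numeric(length(system$nodes))
  for (i in seq_len(nrow(positions))) {
    j <- which.min(colSums((t(pos) - positions[i, ])^2))
    s[j] <- s[j] + currents[i]
  }
  if (abs(sum(s)) > 1e-12 * max(abs(s), 1e-300))
    stop("opposite point sources collapsed onto the same voxel")
  phi <- solve_nodal(system, s, tol = tol)
  as_potential_field(system, phi)
}

#' Trilinear interpolation of a potential field
#'
#' Values outside the conductor fall back to the nearest conducting-voxel
#' value so interpolation cells straddling the boundary stay usable.
#' @keywords internal
interp_phi <- function(field, points) {
  n <- dim(field$phi)
  h <- field$model$spacing
  vol <- field$phi
  pts <- matrix(points, ncol = 3)
  g <- pts / h + 0.5           # voxel-center grid coordinates (1-based)
  i0 <- pmin(pmax(floor(g), 1), matrix(rep(n - 1L, each = nrow(pts)), ncol = 3))
  fr <- g - i0
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  val <- function(ix, iy, iz) {
    v <- vol[cbind(ix, iy, iz)]
    v
  }
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * val(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))
    nodes_pos <- voxel_centers(field$model, which(!is.na(vol)))
    vals <- vol[!is.na(vol)]
    for (b in bad) {
      j <- which.min(colSums((t(nodes_pos) - pts[b, ])^2))
      out[b] <- vals[j]
    }
  }
  out
}

#' Potential gradient at arbitrary points
#'
#' Central differences of the trilinearly interpolated potential, sampled
#' one grid spacing either side per axis (the same stencil scale as the
#' two-monopole dipole representation); volts per meter.
#' @keywords internal
grad_phi <- function(field, points) {
  h <- field$model$spacing
  pts <- matrix(points, ncol = 3)
  g <- matrix(0, nrow(pts), 3)
  for (k in 1:3) {
    dp <- dm <- pts
    dp[, k] <- dp[, k] + h
    dm[, k] <- dm[, k] - h
    g[, k] <- (interp_phi(field, dp) - interp_phi(field, dm)) / (2 * h / 1000)
  }
  g
}

#' Current density field J = -sigma grad phi
#'
#' Central differences on the grid where both axis neighbours conduct,
#' one-sided differences at conductor boundaries; exactly zero in air.
#'
#' @param model the \code{voxel_head_model} the field was solved on.
#' @param field a \code{potential_field}.
#' @return object of class \code{current_density_field} with arrays
#'   \code{jx}, \code{jy}, \code{jz} (A/m2) and \code{magnitude}.
#' @export
current_density <- function(model, field) {
  if (!all(dim(field$phi) == model$dim)) stop("field/model shape mismatch")
  phi <- field$phi
  h_m <- model$spacing / 1000
  n <- model$dim
  J <- list()
  for (k in 1:3) {
    up <- shift_arr(phi, k, -1L)   # value at i+1
    dn <- shift_arr(phi, k, +1L)   # value at i-1
    ctr <- phi
    g <- (up - dn) / (2 * h_m)
    fwd <- (up - ctr) / h_m
    bwd <- (ctr - dn) / h_m
    g[is.na(g)] <- fwd[is.na(g)]
    g[is.na(g)] <- bwd[is.na(g)]
    g[is.na(g)] <- 0
    J[[k]] <- -model$sigma * g
    J[[k]][is.na(phi)] <- 0
  }
  structure(list(jx = J[[1]], jy = J[[2]], jz = J[[3]],
                 magnitude = sqrt(J[[1]]^2 + J[[2]]^2 + J[[3]]^2)),
            class = "current_density_field")
}

# shift an array along axis k by s voxels, padding with NA
shift_arr <- function(a, k, s) {
  n <- dim(a)
  out <- array(NA_real_, n)
  src <- dst <- lapply(n, seq_len)
  if (s > 0) { dst[[k]] <- (1 + s):n[k]; src[[k]] <- 1:(n[k] - s) }
  else if (s < 0) { dst[[k]] <- 1:(n[k] + s); src[[k]] <- (1 - s):n[k] }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src)))))
}

#' Write a potential field as NIfTI
#' @param field a \code{potential_field}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_potential_nifti <- function(field, path) {
  vol <- field$phi
  attr(vol, "pixdim") <- rep(field$model$spacing, 3)
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
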