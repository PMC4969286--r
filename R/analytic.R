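#' Analytic potential in a concentric-sphere conductor
#'
#' Legendre-series solution of the quasi-static current-flow equation for
#' isotropic concentric shells, used as the independent oracle for the
#' finite-difference solver. Supported sources: interior point monopoles
#' (zero-sum set, all inside the innermost shell), an interior current
#' dipole (evaluated as two tightly spaced monopoles, 1e-3 mm apart), and
#' surface injection electrodes. Per harmonic degree the radial
#' coefficients of every layer solve a small transfer system enforcing
#' continuity of potential and radial current at each interface, zero
#' outward flux at the outer boundary (or the injected current density for
#' surface electrodes), and regularity at the center. Surface-electrode
#' series converge slowly, so the closed-form homogeneous-sphere kernel is
#' summed exactly and only the (geometrically decaying) multilayer
#' correction is summed term by term.
#'
#' @param spec a [shell_spec()] (concentric by construction; the only
#'   geometry supported).
#' @param source list: \code{type} one of \code{"monopoles"},
#'   \code{"dipole"}, \code{"injection"}; for monopoles/injection,
#'   \code{positions} (k x 3 mm) and \code{currents} (amperes, zero-sum);
#'   for dipole, \code{position} (mm) and \code{moment} (A m, 3-vector).
#' @param obs observation points, n x 3 mm (inside or on the outer sphere).
#' @param table conductivity table mapping shell tissues to S/m.
#' @param max_order series truncation order.
#' @param rel_tol stop when the running tail falls below this relative size.
#' @return potential in volts at each observation point, average-referenced
#'   over the observation set is NOT applied (free-space zero convention).
#' @export
analytic_shell_potential <- function(spec, source, obs,
                                     table = conductivity_table(),
                                     max_order = 400, rel_tol = 1e-10) {
  stopifnot(inherits(spec, "shell_spec"))
  sig <- unname(table[spec$tissues])
  if (any(sig <= 0)) stop("all shells must conduct")
  R <- spec$radii / 1000                 # m
  L <- length(R)
  RL <- R[L]
  center <- if (is.null(spec$center)) c(0, 0, 0) else spec$center
  obs <- sweep(matrix(obs, ncol = 3), 2, center) / 1000
  robs <- sqrt(rowSums(obs^2))
  if (any(robs > RL * (1 + 1e-9))) stop("observation point outside the outer sphere")
  layer_of <- findInterval(robs * (1 - 1e-12), R) + 1L
  layer_of[layer_of > L] <- L

  if (source$type == "dipole") {
    delta <- 1e-6                        # m
    mhat <- source$moment / sqrt(sum(source$moment^2))
    I0 <- sqrt(sum(source$moment^2)) / delta
    p <- matrix(source$position, ncol = 3)
    source <- list(type = "monopoles",
                   positions = rbind(p + mhat * delta / 2 * 1000,
                                     p - mhat * delta / 2 * 1000),
                   currents = c(I0, -I0))
  }
  srcpos <- sweep(matrix(source$positions, ncol = 3), 2, center) / 1000
  cur <- source$currents
  if (abs(sum(cur)) > 1e-9 * max(abs(cur))) stop("source currents must sum to zero")
  rb <- sqrt(rowSums(srcpos^2))

  interior <- source$type == "monopoles"
  if (interior && any(rb >= R[1] / RL * RL))
    stop("interior monopoles must lie inside the innermost shell")
  if (source$type == "injection" && any(abs(rb - RL) > 1e-3 * RL))
    stop("injection electrodes must lie on the outer surface")

  rho_ifc <- R / RL
  u_obs <- pmax(robs / RL, 1e-12)
  # per-source geometry
  bhat <- srcpos / ifelse(rb > 0, rb, 1)
  cosg <- matrix(0, nrow(obs), nrow(srcpos))
  ohat <- obs / ifelse(robs > 0, robs, 1)
  for (s in seq_len(nrow(srcpos))) cosg[, s] <- ohat %*% bhat[s, ]
  beta <- rb / RL

  V <- numeric(nrow(obs))
  if (!interior) {
    # closed-form homogeneous-sphere kernel at any interior radius
    # (outer-layer conductivity); the series then only sums the
    # geometrically decaying multilayer correction
    sL <- sig[L]
    for (s in seq_len(nrow(srcpos))) {
      x <- cosg[, s]
      d <- sqrt(pmax(1 - 2 * u_obs * x + u_obs^2, 1e-30))
      V <- V + cur[s] / (4 * pi * sL * RL) *
        (2 * (1 / d - 1) + log(2 / pmax(1 - u_obs * x + d, 1e-30)))
    }
  }

  # Legendre recurrence per source
  Pm1 <- matrix(1, nrow(obs), nrow(srcpos))          # P_0
  Pn <- cosg                                          # P_1
  run_max <- rep(1e-300, nrow(obs))
  quiet <- 0L
  for (n in seq_len(max_order)) {
    sol <- shell_mode_coeffs(n, rho_ifc, sig, RL, interior)
    add <- numeric(nrow(obs))
    for (s in seq_len(nrow(srcpos))) {
      if (interior) {
        cs <- cur[s] / (4 * pi * sig[1] * RL)
        amp <- eval_mode(sol$interior, layer_of, u_obs, n, cs, beta[s])
      } else {
        fn <- cur[s] * (2 * n + 1) / (4 * pi * RL^2)
        ch <- cur[s] * (2 * n + 1) / (4 * pi * sig[L] * RL * n)
        amp <- fn * eval_mode_surface(sol$surface, layer_of, u_obs, n) -
          ch * u_obs^n
      }
      add <- add + amp * Pn[, s]
    }
    V <- V + add
    run_max <- pmax(run_max, abs(V))
    quiet <- if (max(abs(add) / run_max) < rel_tol) quiet + 1L else 0L
    if (quiet >= 3L) break
    Pnext <- ((2 * n + 1) * cosg * Pn - n * Pm1) / (n + 1)
    Pm1 <- Pn
    Pn <- Pnext
  }
  V
}

# Solve the per-degree radial transfer system.
# Layers j=1..L with scaled interface radii rho_ifc (rho_L = 1). The layer
# potentials use per-layer scaled basis functions that stay O(1) on their
# layer, which keeps the transfer matrix well conditioned at high degree:
#   V_j(u) = a_j (u/rho_j)^n + b_j (rho_{j-1}/u)^(n+1)
# (no b term in layer 1; its source kernel is handled separately). The
# known layer-1 source term is u^-(n+1) per unit multipole coefficient.
shell_mode_coeffs <- function(n, rho_ifc, sig, RL, interior) {
  L <- length(rho_ifc)
  rin <- c(0, rho_ifc[-L])              # inner radius of each layer
  nun <- 2 * L - 1                      # a_1, a_2, b_2, ..., a_L, b_L
  Aidx <- function(j) if (j == 1) 1L else 2L * (j - 1L)
  Bidx <- function(j) 2L * j - 1L       # j >= 2
  fa <- function(j, u) (u / rho_ifc[j])^n
  fad <- function(j, u) (n / u) * (u / rho_ifc[j])^n
  fb <- function(j, u) (rin[j] / u)^(n + 1)
  fbd <- function(j, u) -((n + 1) / u) * (rin[j] / u)^(n + 1)
  M <- matrix(0, nun, nun)
  rhs_int <- numeric(nun)
  rhs_srf <- numeric(nun)
  row <- 0L
  for (j in seq_len(L - 1)) {
    r <- rho_ifc[j]
    row <- row + 1L                      # potential continuity
    M[row, Aidx(j)] <- fa(j, r)
    if (j > 1) M[row, Bidx(j)] <- fb(j, r)
    M[row, Aidx(j + 1)] <- -fa(j + 1, r)
    M[row, Bidx(j + 1)] <- -fb(j + 1, r)
    if (j == 1) rhs_int[row] <- -r^-(n + 1)       # move known source term
    row <- row + 1L                      # radial current continuity
    M[row, Aidx(j)] <- sig[j] * fad(j, r)
    if (j > 1) M[row, Bidx(j)] <- sig[j] * fbd(j, r)
    M[row, Aidx(j + 1)] <- -sig[j + 1] * fad(j + 1, r)
    M[row, Bidx(j + 1)] <- -sig[j + 1] * fbd(j + 1, r)
    if (j == 1) rhs_int[row] <- sig[1] * (n + 1) * r^-(n + 2)
  }
  row <- row + 1L                        # outer: sig_L dV/dr = f
  M[row, Aidx(L)] <- sig[L] * fad(L, 1)
  if (L > 1) M[row, Bidx(L)] <- sig[L] * fbd(L, 1)
  if (L == 1) rhs_int[row] <- sig[1] * (n + 1)    # from the unit source term
  rhs_srf[row] <- RL                              # d/dr = (1/RL) d/du
  out <- list()
  if (interior) {
    sol <- solve(M, rhs_int)
    a <- numeric(L); b <- numeric(L)
    a[1] <- sol[1]
    if (L > 1) for (j in 2:L) { a[j] <- sol[Aidx(j)]; b[j] <- sol[Bidx(j)] }
    out$interior <- list(a = a, b = b, rho_out = rho_ifc, rho_in = rin)
  } else {
    sol <- solve(M, rhs_srf)
    a <- numeric(L); b <- numeric(L)
    a[1] <- sol[1]
    if (L > 1) for (j in 2:L) { a[j] <- sol[Aidx(j)]; b[j] <- sol[Bidx(j)] }
    out$surface <- list(a = a, b = b, rho_out = rho_ifc, rho_in = rin)
  }
  out
}

# degree-n radial profile of the (source-free) surface-injection problem,
# per unit Neumann coefficient
eval_mode_surface <- function(cf, layer_of, u, n) {
  a <- cf$a[layer_of]
  out <- a * (u / cf$rho_out[layer_of])^n
  deep <- layer_of > 1L
  if (any(deep)) {
    lo <- layer_of[deep]
    out[deep] <- out[deep] + cf$b[lo] * (cf$rho_in[lo] / u[deep])^(n + 1)
  }
  out
}

# Evaluate the degree-n radial profile at each observation point for an
# interior source of multipole strength cs * beta^n at scaled radius beta.
# In layer 1 the particular (source) term uses the two-sided multipole
# kernel min(u,beta)^n / max(u,beta)^(n+1); outer layers use the solved
# scaled b term.
eval_mode <- function(cf, layer_of, u, n, cs, beta) {
  Sn <- cs * beta^n
  a <- cf$a[layer_of]
  hom <- Sn * a * (u / cf$rho_out[layer_of])^n
  src <- numeric(length(u))
  in1 <- layer_of == 1L
  if (any(in1)) {
    u1 <- u[in1]
    src[in1] <- cs * ifelse(u1 >= beta,
                            beta^n / u1^(n + 1),
                            if (beta > 0) u1^n / beta^(n + 1) else 0)
  }
  if (any(!in1)) {
    lo <- layer_of[!in1]
    src[!in1] <- Sn * cf$b[lo] * (cf$rho_in[lo] / u[!in1])^(n + 1)
  }
  hom + src
}
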