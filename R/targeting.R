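#' Safety limits for current injection
#'
#' Defaults follow dense-array TES practice: at most 200 uA through any
#' single 1 cm2 electrode and at most 2 mA total (one-sided sum).
#'
#' @param max_channel_uA per-electrode cap, microamperes.
#' @param max_total_mA total (anodal-side) cap, milliamperes.
#' @return object of class \code{safety_limits}.
#' @export
safety_limits <- function(max_channel_uA = 200, max_total_mA = 2.0) {
  if (max_channel_uA <= 0 || max_total_mA <= 0) stop("limits must be > 0")
  if (max_channel_uA > max_total_mA * 1000)
    stop("per-channel cap cannot exceed the total cap")
  structure(list(max_channel_uA = max_channel_uA, max_total_mA = max_total_mA),
            class = "safety_limits")
}

#' Scalp projection of a cortical target
#'
#' Returns the per-electrode voltage topography of a unit dipole at the
#' target patch, oriented along the patch's averaged normal: the lead-field
#' column, negated for cortical-surface-cathodal polarity. Sorting
#' electrodes by this topography is the reciprocity recipe for choosing
#' injection electrodes. Voltages are average-referenced (they sum to zero
#' over electrodes).
#'
#' @param lfm a \code{lead_field}.
#' @param patch_id target patch id.
#' @param polarity \code{"anodal"} or \code{"cathodal"}
#'   (cortical-surface sign convention, see the package vignette).
#' @return named numeric vector of voltages, one per electrode.
#' @export
project_target_to_scalp <- function(lfm, patch_id,
                                    polarity = c("anodal", "cathodal")) {
  polarity <- match.arg(polarity)
  p <- match(patch_id, lfm$patch_ids)
  if (is.na(p)) stop("unknown patch id: ", patch_id)
  v <- lfm$matrix[, p]
  if (polarity == "cathodal") v <- -v
  names(v) <- lfm$electrode_ids
  v
}

#' Select and weight injection electrodes
#'
#' Reciprocity-based montage construction, stage 1: the N electrodes with
#' the largest positive projected voltages become sources (anodes) and the
#' M electrodes with the largest-magnitude negative voltages become sinks
#' (cathodes). The largest source voltage gets weight +1, the largest-
#' magnitude sink voltage weight -1, the rest scale proportionally, and
#' each weight is multiplied by the per-channel current cap. Ranking ties
#' break toward the lower electrode index.
#'
#' @param voltages per-electrode projected voltages (from
#'   [project_target_to_scalp()]).
#' @param N number of source electrodes (>= 1).
#' @param M number of sink electrodes (>= 1).
#' @param limits a [safety_limits()].
#' @return object of class \code{montage}: data.frame \code{electrode}
#'   (index), \code{id}, \code{current_uA}, with attributes \code{N},
#'   \code{M}, \code{balanced = FALSE}.
#' @export
select_and_weight <- function(voltages, N, M, limits = safety_limits()) {
  if (N < 1 || M < 1) stop("N and M must be >= 1")
  pos <- which(voltages > 0)
  neg <- which(voltages < 0)
  if (length(pos) < N || length(neg) < M)
    stop("insufficient electrodes of required polarity: ",
         length(pos), " positive, ", length(neg), " negative")
  src <- pos[order(-voltages[pos], pos)][seq_len(N)]
  snk <- neg[order(-abs(voltages[neg]), neg)][seq_len(M)]
  w_src <- voltages[src] / voltages[src][1]
  w_snk <- -abs(voltages[snk]) / abs(voltages[snk])[1]
  cur <- c(w_src, w_snk) * limits$max_channel_uA
  ids <- names(voltages)
  if (is.null(ids)) ids <- as.character(seq_along(voltages))
  out <- data.frame(electrode = c(src, snk), id = ids[c(src, snk)],
                    current_uA = unname(cur), stringsAsFactors = FALSE)
  structure(out, N = N, M = M, balanced = FALSE, limits = limits,
            class = c("montage", "data.frame"))
}

#' Balance and cap a montage
#'
#' Stage 2 of montage construction. First the side (sources or sinks)
#' carrying the larger total is scaled down by the ratio of side sums so
#' anodal and cathodal currents sum to exactly zero. Then, if the one-sided
#' total exceeds the smaller of the requested total and the safety total,
#' all currents are scaled down by that ratio. Per-channel caps cannot be
#' violated because both steps only shrink magnitudes.
#'
#' @param montage a [select_and_weight()] montage.
#' @param requested_total_mA total current requested by the plan,
#'   milliamperes (one-sided).
#' @param limits a [safety_limits()].
#' @return the balanced \code{montage} (attribute \code{balanced = TRUE},
#'   plus \code{total_uA}, the one-sided sum).
#' @export
balance_and_cap <- function(montage, requested_total_mA,
                            limits = safety_limits()) {
  if (requested_total_mA <= 0) stop("requested total must be > 0")
  cur <- montage$current_uA
  s_pos <- sum(cur[cur > 0])
  s_neg <- sum(-cur[cur < 0])
  if (s_pos > s_neg) {
    cur[cur > 0] <- cur[cur > 0] * s_neg / s_pos
  } else if (s_neg > s_pos) {
    cur[cur < 0] <- cur[cur < 0] * s_pos / s_neg
  }
  side <- sum(cur[cur > 0])
  cap <- min(requested_total_mA * 1000, limits$max_total_mA * 1000)
  if (side > cap) cur <- cur * cap / side
  montage$current_uA <- cur
  attr(montage, "balanced") <- TRUE
  attr(montage, "total_uA") <- sum(cur[cur > 0])
  montage
}

#' Plan a montage for a cortical target
#'
#' Convenience wrapper: project, select/weight, balance/cap.
#'
#' @inheritParams project_target_to_scalp
#' @inheritParams select_and_weight
#' @inheritParams balance_and_cap
#' @return a balanced \code{montage}.
#' @export
plan_montage <- function(lfm, patch_id, polarity = "anodal", N = 8, M = 8,
                         requested_total_mA = 2.0, limits = safety_limits()) {
  v <- project_target_to_scalp(lfm, patch_id, polarity)
  m <- select_and_weight(v, N, M, limits)
  balance_and_cap(m, requested_total_mA, limits)
}

#' @export
print.montage <- function(x, ...) {
  cat("montage:", sum(x$current_uA > 0), "sources,", sum(x$current_uA < 0),
      "sinks; side sum", sprintf("%.2f uA", sum(x$current_uA[x$current_uA > 0])),
      "\n")
  print.data.frame(x)
  invisible(x)
}

#' Build the matched sham (placebo) montage
#'
#' Within the active montage's source cluster, the electrode with the
#' lowest current magnitude keeps its role and its nearest neighbour in the
#' full array becomes its local counter-electrode; likewise in the sink
#' cluster. Each local pair carries 100 uA (+100/-100), so the sham totals
#' 200 uA positive and sums to zero; the shallow local loops spare the
#' cortical target. If the nearest neighbour already carries active current
#' of the opposite side, the next-nearest free electrode is used (with a
#' warning).
#'
#' @param active a balanced \code{montage}.
#' @param electrodes the full \code{electrode_set}.
#' @param pair_uA current per pair, microamperes.
#' @return a \code{montage} with two pairs.
#' @export
build_sham_montage <- function(active, electrodes, pair_uA = 100) {
  cur <- active$current_uA
  if (!any(cur > 0) || !any(cur < 0)) stop("active montage needs both polarities")
  pos <- as.matrix(electrodes[, c("x", "y", "z")])
  taken <- active$electrode
  pick_pair <- function(side_sign) {
    side <- active$electrode[sign(cur) == side_sign]
    low <- side[which.min(abs(cur[sign(cur) == side_sign]))]
    d <- colSums((t(pos) - pos[low, ])^2)
    d[low] <- Inf
    ord <- order(d)
    opposite <- active$electrode[sign(cur) == -side_sign]
    nb <- ord[1]
    if (nb %in% opposite) {
      warning("nearest neighbour of sham electrode carries opposite active ",
              "current; using next nearest")
      nb <- ord[which(!(ord %in% opposite))[1]]
    }
    c(low, nb)
  }
  sp <- pick_pair(1)    # source cluster: low-current source +, neighbour -
  kp <- pick_pair(-1)   # sink cluster: low-current sink -, neighbour +
  ids <- electrodes$id
  out <- data.frame(electrode = c(sp, kp),
                    id = ids[c(sp, kp)],
                    current_uA = c(pair_uA, -pair_uA, -pair_uA, pair_uA),
                    stringsAsFactors = FALSE)
  structure(out, N = 2L, M = 2L, balanced = TRUE, total_uA = 2 * pair_uA,
            class = c("montage", "data.frame"))
}

#' Montage currents as a full per-electrode vector (uA)
#' @param montage a \code{montage}.
#' @param n_electrodes array size.
#' @return numeric vector of length \code{n_electrodes}.
#' @export
montage_vector <- function(montage, n_electrodes) {
  v <- numeric(n_electrodes)
  v[montage$electrode] <- montage$current_uA
  v
}

#' Evaluate a montage on the cortex
#'
#' Solves the forward problem for the montage currents and decomposes the
#' current density at every patch centroid into a signed normal component
#' and a tangential magnitude. The signed normal component is reported
#' along the anodal direction (scalp toward cortex, i.e. minus the outward
#' patch normal), so positive values mean cortical-surface-anodal current
#' at that patch.
#'
#' @param system an \code{fdm_system}.
#' @param electrodes an \code{electrode_set}.
#' @param montage a zero-sum \code{montage}.
#' @param parcellation a \code{parcellation}.
#' @param tol CG tolerance.
#' @param threshold_lowest drop (set NA) the lowest fraction of |normal|
#'   values in the \code{j_normal_display} column, the display convention
#'   used to highlight high-dose cortex; 0 disables.
#' @return data.frame: \code{patch}, \code{j_normal} (A/m2, anodal
#'   positive), \code{j_tangential} (A/m2), \code{j_normal_display}.
#' @export
evaluate_montage <- function(system, electrodes, montage, parcellation,
                             tol = 1e-8, threshold_lowest = 0) {
  if (any(montage$electrode > nrow(electrodes)))
    stop("montage references unknown electrodes")
  pat <- montage_vector(montage, nrow(electrodes))
  if (abs(sum(pat)) > 1e-9 * max(abs(pat))) stop("montage must sum to zero")
  fld <- solve_injection(system, electrodes, pat, tol = tol)
  pts <- as.matrix(parcellation$patches[, c("x", "y", "z")])
  nrm <- as.matrix(parcellation$patches[, c("nx", "ny", "nz")])
  g <- grad_phi(fld, pts)                       # V/m
  sig <- apply(pts, 1, function(p) sigma_at(system$model, p))
  jvec <- -sig * g                              # J = -sigma grad phi
  j_out <- rowSums(jvec * nrm)                  # along outward normal
  j_normal <- -j_out                            # anodal (inward) positive
  tang <- jvec - j_out * nrm
  j_tangential <- sqrt(rowSums(tang^2))
  disp <- j_normal
  if (threshold_lowest > 0) {
    cut <- stats::quantile(abs(j_normal), threshold_lowest)
    disp[abs(j_normal) < cut] <- NA_real_
  }
  data.frame(patch = parcellation$patches$id,
             j_normal = j_normal,
             j_tangential = j_tangential,
             j_normal_display = disp)
}

#' Target dose of a montage from a per-electrode basis
#'
#' @param basis a [target_dose_basis()] vector (A/m2 per A).
#' @param montage a \code{montage}.
#' @return signed normal current density at the target, A/m2
#'   (anodal positive).
#' @export
montage_target_dose <- function(basis, montage) {
  v <- montage_vector(montage, length(basis))
  sum(basis * v) * 1e-6                 # uA -> A
}

#' Random constraint-matched montage
#'
#' Draws a zero-sum montage with the same source/sink counts, per-channel
#' cap and one-sided total as a reference montage, used for Monte-Carlo
#' comparison against the reciprocity montage.
#'
#' @param n_electrodes array size.
#' @param N,M source and sink counts.
#' @param total_uA one-sided total, microamperes.
#' @param limits a [safety_limits()].
#' @return a \code{montage}.
#' @export
random_montage <- function(n_electrodes, N, M, total_uA,
                           limits = safety_limits()) {
  cap <- limits$max_channel_uA
  if (total_uA > N * cap || total_uA > M * cap)
    stop("total not reachable under the per-channel cap")
  sel <- sample.int(n_electrodes, N + M)
  draw_side <- function(k) {
    # uniform weights rescaled to the total, redrawn if any entry busts the cap
    repeat {
      w <- stats::runif(k)
      cur <- w / sum(w) * total_uA
      if (all(cur <= cap)) return(cur)
    }
  }
  out <- data.frame(electrode = sel,
                    id = as.character(sel),
                    current_uA = c(draw_side(N), -draw_side(M)),
                    stringsAsFactors = FALSE)
  structure(out, N = N, M = M, balanced = TRUE, total_uA = total_uA,
            class = c("montage", "data.frame"))
}

#' Write / read montages
#' @param montage a \code{montage}.
#' @param path output path (.json or .csv decided by extension).
#' @return \code{path} / a \code{montage}.
#' @export
write_montage <- function(montage, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(N = attr(montage, "N"), M = attr(montage, "M"),
                              total_uA = attr(montage, "total_uA"),
                              channels = as.data.frame(montage)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(montage), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- obj$channels
    structure(out, N = obj$N, M = obj$M, balanced = TRUE,
              total_uA = obj$total_uA, class = c("montage", "data.frame"))
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    structure(out, N = sum(out$current_uA > 0), M = sum(out$current_uA < 0),
              balanced = TRUE, total_uA = sum(out$current_uA[out$current_uA > 0]),
              class = c("montage", "data.frame"))
  }
}
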