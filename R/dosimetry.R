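#' Stimulation protocol descriptor
#'
#' Waveform descriptor from which injection time and total charge are
#' derived. Kinds: continuous direct current (\code{tdcs}), pulsed current
#' (\code{tpcs}: rectangular pulses of \code{pulse_s} at a repetition
#' period of \code{pulse_s + ipi_s}, or \code{1/freq_hz} when the
#' inter-pulse interval is not given), slow-oscillatory direct current
#' (\code{sotdcs}: sinusoid from 0 to the peak current, flowing for the
#' whole session), a truncated \code{sham} train of \code{n_pulses}, and a
#' two-phase direct-current \code{conditioning} block.
#'
#' @param kind one of \code{"tdcs"}, \code{"tpcs"}, \code{"sotdcs"},
#'   \code{"sham"}, \code{"conditioning"}.
#' @param total_mA one-sided total current, mA (peak current for sotdcs).
#' @param duration_s total session duration, s (for conditioning: sum of
#'   the phase durations).
#' @param pulse_s pulse duration, s (tpcs / sham).
#' @param ipi_s inter-pulse interval, s; alternative to \code{freq_hz}.
#' @param freq_hz pulse repetition rate, Hz; when both are supplied they
#'   must agree (period = pulse + IPI) to 1 percent.
#' @param n_pulses number of pulses in a sham train.
#' @param osc_hz oscillation frequency for sotdcs (descriptive only; the
#'   charge of a 0-to-peak sinusoid does not depend on it).
#' @param area_cm2 total electrode contact area, cm2.
#' @param label free-text name.
#' @return object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(kind, total_mA, duration_s, pulse_s = NULL,
                          ipi_s = NULL, freq_hz = NULL, n_pulses = NULL,
                          osc_hz = NULL, area_cm2 = NA, label = kind) {
  kind <- match.arg(kind, c("tdcs", "tpcs", "sotdcs", "sham", "conditioning"))
  if (duration_s <= 0) stop("duration must be > 0")
  if (total_mA < 0) stop("total current must be >= 0")
  if (kind %in% c("tpcs", "sham")) {
    if (is.null(pulse_s) || pulse_s <= 0) stop(kind, " needs a pulse duration")
    if (is.null(ipi_s) && is.null(freq_hz)) stop(kind, " needs ipi_s or freq_hz")
    if (!is.null(ipi_s) && !is.null(freq_hz)) {
      if (abs((pulse_s + ipi_s) - 1 / freq_hz) > 0.01 / freq_hz)
        stop("inconsistent frequency and inter-pulse interval")
    }
    if (is.null(ipi_s)) ipi_s <- 1 / freq_hz - pulse_s
    if (ipi_s < 0) stop("pulse duration exceeds the repetition period")
    if (is.null(freq_hz)) freq_hz <- 1 / (pulse_s + ipi_s)
  }
  if (kind == "sham" && is.null(n_pulses)) stop("sham needs n_pulses")
  structure(list(kind = kind, total_mA = total_mA, duration_s = duration_s,
                 pulse_s = pulse_s, ipi_s = ipi_s, freq_hz = freq_hz,
                 n_pulses = n_pulses, osc_hz = osc_hz, area_cm2 = area_cm2,
                 label = label),
            class = "stim_protocol")
}

#' Total current-injection time of a protocol
#'
#' Continuous kinds (tdcs, sotdcs, conditioning) inject for the whole
#' duration; pulsed kinds inject for the duty-cycle fraction
#' pulse / (pulse + IPI); a sham train injects n_pulses * pulse.
#'
#' @param p a [stim_protocol()].
#' @return seconds.
#' @export
injection_time <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  switch(p$kind,
         tdcs = p$duration_s,
         sotdcs = p$duration_s,
         conditioning = p$duration_s,
         tpcs = p$duration_s * p$pulse_s / (p$pulse_s + p$ipi_s),
         sham = p$n_pulses * p$pulse_s)
}

#' Total charge of a protocol
#'
#' Charge = current x injection time for rectangular waveforms. For
#' slow-oscillatory DC the sinusoid runs from 0 to the peak, so its
#' time-averaged current is half the peak and the charge is
#' peak / 2 x duration (a stated convention of this package, chosen to
#' make published so-tDCS charge figures come out of their printed peak
#' currents and durations).
#'
#' @param p a [stim_protocol()].
#' @return millicoulombs.
#' @export
total_charge <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  if (p$kind == "sotdcs") p$total_mA / 2 * p$duration_s
  else p$total_mA * injection_time(p)
}

#' Dose report for a protocol
#'
#' @param p a [stim_protocol()].
#' @param n_electrodes,area_per_cm2 electrode count and per-electrode area
#'   for the current-density figure; taken from \code{p$area_cm2} as a
#'   single total area when omitted.
#' @return data.frame: injection time (s), total charge (mC), mean current
#'   density (mA/cm2, unrounded).
#' @export
dose_report <- function(p, n_electrodes = NULL, area_per_cm2 = NULL) {
  ti <- injection_time(p)
  q <- total_charge(p)
  dens <- if (!is.null(n_electrodes) && !is.null(area_per_cm2))
    mean_current_density(p$total_mA, n_electrodes, area_per_cm2, round2 = FALSE)
  else if (!is.na(p$area_cm2)) p$total_mA / p$area_cm2 else NA_real_
  data.frame(label = p$label, kind = p$kind, total_mA = p$total_mA,
             injection_time_s = ti, total_charge_mC = q,
             current_density_mA_cm2 = dens)
}

#' Mean current density over the electrode set
#'
#' Total current divided by total contact area, optionally rounded half-up
#' to two decimals (the convention used when quoting densities like
#' 0.15 mA/cm2 for 1.16 mA over eight 1 cm2 electrodes).
#'
#' @param total_mA one-sided total current, mA.
#' @param n_electrodes electrode count per side.
#' @param area_per_cm2 contact area per electrode, cm2.
#' @param round2 round half-up to 2 decimals.
#' @return mA/cm2.
#' @export
mean_current_density <- function(total_mA, n_electrodes, area_per_cm2 = 1.0,
                                 round2 = TRUE) {
  if (n_electrodes <= 0 || area_per_cm2 <= 0) stop("counts and areas must be > 0")
  d <- total_mA / (n_electrodes * area_per_cm2)
  if (round2) round_half_up(d, 2) else d
}

# decimal half-up rounding with a one-ulp-scale guard against binary
# representation of exact decimal halves (0.145 stored as 0.14499...)
round_half_up <- function(x, digits) {
  p <- 10^digits
  y <- x * p
  floor(y + 0.5 + abs(y) * 1e-12) / p
}

#' Named preset protocols
#'
#' The protocols compared in the package's dosimetry tables: the
#' slow-pulse study protocol (tPCS, 1.16 mA cohort-mean total, 100 ms
#' pulses at 0.5 Hz for 17 min), its lidocaine conditioning block
#' (50 uA/electrode, 400 uA total, 30 s per direction) and 5-pulse sham,
#' classic 1 mA tDCS references (60 s anodal; 300 s cathodal), and pulsed /
#' slow-oscillatory comparison protocols (0.7 mA tDCS 600 s; 1.5 mA tPCS
#' with 0.5 s pulses at 50 ms and 650 ms inter-pulse intervals; 0-to-peak
#' slow-oscillatory DC at 0.75 and 1.5 mA for 600 s).
#'
#' @param total_mA override for the study protocol's total current (per-plan
#'   currents vary; 1.16 mA is the cohort mean).
#' @return named list of [stim_protocol()] objects.
#' @export
preset_protocols <- function(total_mA = 1.16) {
  list(
    present_tpcs = stim_protocol("tpcs", total_mA, 1020, pulse_s = 0.1,
                                 freq_hz = 0.5, area_cm2 = 8,
                                 label = "present_tpcs"),
    conditioning = stim_protocol("conditioning", 0.4, 60, area_cm2 = 8,
                                 label = "conditioning"),
    sham = stim_protocol("sham", 0.2, 10, pulse_s = 0.1, freq_hz = 0.5,
                         n_pulses = 5, area_cm2 = 4, label = "sham"),
    nitsche_anodal = stim_protocol("tdcs", 1.0, 60, area_cm2 = 35,
                                   label = "nitsche_anodal"),
    nitsche_cathodal = stim_protocol("tdcs", 1.0, 300, area_cm2 = 35,
                                     label = "nitsche_cathodal"),
    groppa_tdcs = stim_protocol("tdcs", 0.7, 600, area_cm2 = 24,
                                label = "groppa_tdcs"),
    groppa_tpcs_short = stim_protocol("tpcs", 1.5, 300, pulse_s = 0.5,
                                      ipi_s = 0.05, area_cm2 = 24,
                                      label = "groppa_tpcs_short"),
    groppa_tpcs_long = stim_protocol("tpcs", 1.5, 600, pulse_s = 0.5,
                                     ipi_s = 0.65, area_cm2 = 24,
                                     label = "groppa_tpcs_long"),
    sotdcs_low = stim_protocol("sotdcs", 0.75, 600, osc_hz = 0.8,
                               area_cm2 = 12, label = "sotdcs_low"),
    sotdcs_high = stim_protocol("sotdcs", 1.5, 600, osc_hz = 0.8,
                                area_cm2 = 12, label = "sotdcs_high"))
}

#' Dose table over a set of protocols
#'
#' @param protocols list of [stim_protocol()] (default: all presets).
#' @return data.frame, one [dose_report()] row per protocol.
#' @export
dose_table <- function(protocols = preset_protocols()) {
  do.call(rbind, lapply(protocols, dose_report))
}
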