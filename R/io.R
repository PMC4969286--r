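#' Read electrode positions from CSV or .sfp-style text
#'
#' CSV files need columns id,x,y,z and optionally area (cm2, default 1.0).
#' .sfp-style files are whitespace-separated label x y z lines without a
#' header. Coordinates are millimeters in the corner-origin grid frame.
#'
#' @param path input file; format decided by extension (.csv vs anything
#'   else).
#' @return an \code{electrode_set} data.frame.
#' @export
load_electrode_positions <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", "z")
    if (!all(need %in% names(d)))
      stop("electrode CSV needs columns id,x,y,z (got: ",
           paste(names(d), collapse = ","), ")")
    if (!"area" %in% names(d)) d$area <- 1.0
    d <- d[, c("id", "x", "y", "z", "area")]
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\\s+")
    nf <- lengths(parts)
    if (any(nf < 4))
      stop("malformed electrode row(s) at line ",
           paste(which(nf < 4), collapse = ", "))
    d <- data.frame(id = vapply(parts, `[`, "", 1),
                    x = as.numeric(vapply(parts, `[`, "", 2)),
                    y = as.numeric(vapply(parts, `[`, "", 3)),
                    z = as.numeric(vapply(parts, `[`, "", 4)),
                    area = ifelse(nf >= 5,
                                  as.numeric(vapply(parts, function(p)
                                    if (length(p) >= 5) p[5] else "1", "")), 1.0),
                    stringsAsFactors = FALSE)
  }
  if (anyNA(d$x) || anyNA(d$y) || anyNA(d$z)) {
    bad <- which(is.na(d$x) | is.na(d$y) | is.na(d$z))
    stop("malformed electrode row(s) at line ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(d$id))
    stop("duplicate electrode id: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  class(d) <- c("electrode_set", "data.frame")
  d
}

#' Write an electrode set
#' @param electrodes an \code{electrode_set}.
#' @param path output path (.csv, or .sfp-style otherwise).
#' @return \code{path}, invisibly.
#' @export
write_electrode_positions <- function(electrodes, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(as.data.frame(electrodes)[, c("id", "x", "y", "z", "area")],
                     path, row.names = FALSE)
  } else {
    writeLines(sprintf("%s\t%.9g\t%.9g\t%.9g\t%.9g", electrodes$id,
                       electrodes$x, electrodes$y, electrodes$z,
                       electrodes$area), path)
  }
  invisible(path)
}

#' Plan configuration
#'
#' Settings for the end-to-end planning pipeline [run_plan()].
#'
#' @param shell a [shell_spec()] for the phantom.
#' @param spacing_mm grid spacing.
#' @param n_electrodes geodesic array size.
#' @param cortex_radius_mm radius of the synthetic spherical cortex mesh.
#' @param cortex_subdiv icosphere subdivisions for the cortex mesh.
#' @param patch_area_cm2 parcellation target area.
#' @param target either a patch id (integer) or a length-3 point (mm)
#'   mapped through [nearest_patch()]; \code{NULL} picks the patch nearest
#'   the +z pole of the cortex.
#' @param polarity "anodal" or "cathodal".
#' @param N,M source and sink counts.
#' @param requested_total_mA requested total current.
#' @param limits a [safety_limits()].
#' @param tol forward-solver tolerance.
#' @param seed RNG seed recorded in the bundle.
#' @return object of class \code{plan_config}.
#' @export
plan_config <- function(shell = shell_spec(), spacing_mm = 4,
                        n_electrodes = 48, cortex_radius_mm = 65,
                        cortex_subdiv = 3, patch_area_cm2 = 4,
                        target = NULL, polarity = "anodal", N = 8, M = 8,
                        requested_total_mA = 2.0, limits = safety_limits(),
                        tol = 1e-8, seed = 1) {
  if (N + M > n_electrodes) stop("N + M cannot exceed the electrode count")
  structure(as.list(environment()), class = "plan_config")
}

#' Run the full planning pipeline
#'
#' phantom -> electrode array -> cortex parcellation -> FDM lead field ->
#' reciprocity montage (+ sham) -> cortical evaluation -> dose report.
#' Deterministic under the configured seed; outputs are written under
#' \code{out_dir} when given (montage JSON + CSV, sham JSON, evaluation
#' CSV, dose CSV, provenance JSON, log).
#'
#' @param config a [plan_config()].
#' @param out_dir output directory or NULL for no files.
#' @return list with all intermediate objects and the output paths.
#' @export
run_plan <- function(config = plan_config(), out_dir = NULL) {
  stopifnot(inherits(config, "plan_config"))
  set.seed(config$seed)
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }
  say("stage phantom: 4-shell voxel model @ ", config$spacing_mm, " mm")
  model <- build_shell_phantom(config$shell, config$spacing_mm)
  electrodes <- place_geodesic_electrodes(model, config$n_electrodes)
  say("stage cortex: parcellating synthetic cortex mesh")
  ctr <- model$center
  mesh <- icosphere(config$cortex_radius_mm, config$cortex_subdiv, center = ctr)
  parc <- parcellate_surface(mesh, config$patch_area_cm2)
  say("stage leadfield: ", nrow(electrodes), " electrode solves")
  system <- assemble_fdm_system(model)
  lfm <- lead_field_from_reciprocity(system, electrodes, parc, tol = config$tol)
  target <- config$target
  if (is.null(target)) target <- nearest_patch(parc, ctr + c(0, 0, config$cortex_radius_mm))
  if (length(target) == 3) target <- nearest_patch(parc, target)
  say("stage plan: target patch ", target, ", polarity ", config$polarity)
  montage <- plan_montage(lfm, target, config$polarity, config$N, config$M,
                          config$requested_total_mA, config$limits)
  sham <- build_sham_montage(montage, electrodes)
  say("stage evaluate: montage forward solve")
  evaluation <- evaluate_montage(system, electrodes, montage, parc,
                                 tol = config$tol, threshold_lowest = 0.5)
  say("stage dose: protocol dosimetry at planned total current")
  proto <- stim_protocol("tpcs", attr(montage, "total_uA") / 1000,
                         1020, pulse_s = 0.1, freq_hz = 0.5,
                         area_cm2 = config$N, label = "planned_tpcs")
  dose <- dose_report(proto, n_electrodes = config$N, area_per_cm2 = 1.0)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      montage_json = write_montage(montage, file.path(out_dir, "montage.json")),
      montage_csv = write_montage(montage, file.path(out_dir, "montage.csv")),
      sham_json = write_montage(sham, file.path(out_dir, "sham.json")),
      evaluation_csv = file.path(out_dir, "evaluation.csv"),
      dose_csv = file.path(out_dir, "dose.csv"),
      provenance = file.path(out_dir, "provenance.json"),
      log = file.path(out_dir, "plan.log"))
    utils::write.csv(evaluation, paths$evaluation_csv, row.names = FALSE)
    utils::write.csv(dose, paths$dose_csv, row.names = FALSE)
    cfg <- config
    cfg$shell <- unclass(cfg$shell)
    cfg$limits <- unclass(cfg$limits)
    jsonlite::write_json(list(config = unclass(cfg),
                              config_hash = config_hash(config),
                              r_version = as.character(getRversion()),
                              package_version =
                                as.character(utils::packageVersion("tesplan"))),
                         paths$provenance, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    writeLines(log, paths$log)
  }
  list(config = config, model = model, electrodes = electrodes, mesh = mesh,
       parcellation = parc, system = system, lead_field = lfm,
       target = target, montage = montage, sham = sham,
       evaluation = evaluation, dose = dose, paths = paths)
}

config_hash <- function(config) {
  cfg <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small stable polynomial hash; provenance only, not cryptographic
  h <- 0
  for (b in utf8ToInt(as.character(txt))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
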