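# End-to-end orchestration: one config in, one structured report out.

#' Default run configuration
#'
#' Assembles the effective configuration for [run_profile()], with the
#' study thresholds as defaults: affinity cut at -6.0 kcal/mol,
#' polar-site cut at LI 10 percent, permeability cuts at 1e-6 and 2e-6
#' cm/s. Any override is echoed in the report.
#'
#' @param ... named overrides; nested lists (`weight`, `pocket`,
#'   `geometry`, `thresholds`, `calibration`) are merged element-wise.
#' @return a named list (class `"run_config"`).
#' @export
run_config <- function(...) {
  base <- list(
    host = NULL, guest = NULL, fragment_table = NULL,
    pose_table = NULL, timecourse = NULL, c0 = NULL,
    weight = list(form = "exponential", cutoff = 10),
    pocket = list(center = c(56.49, 12.97, 9.29), radius = 5, spacing = 1),
    geometry = list(area = 0.336, v_basolateral = 0.9, v_apical = 0.3,
                    v_sample = 0.1),
    temperature = 298.15,
    top_k = 3,
    slope_mode = "derivative_at_zero",
    correct_sampling = TRUE,
    max_time_min = Inf,
    probe_radius = 1.4,
    points_per_atom = 100,
    calibration = list(w_plus = 1, w_minus = 1, intercept = 0),
    thresholds = list(affinity = -6.0, li = 10, papp = c(1e-6, 2e-6)),
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- utils::modifyList(base, over)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be YAML or JSON")
  run_config(raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, ": ", conditionMessage(e), call. = FALSE))
}

#' Profile a host-guest complex end to end
#'
#' Runs the full pipeline on the inputs named in the configuration:
#' pocket polarity of the host cavity (lipophilicity index), logP_MLP for
#' host and guest over their accessible surfaces, docking-pose binding
#' summary with free-energy-to-binding-constant conversion, and Transwell
#' apparent permeability. Any stage failure raises an error naming the
#' stage. The effective configuration is embedded in the report, so a
#' report re-runs to itself.
#'
#' @param config a [run_config()], a config file path, or a plain list of
#'   overrides.
#' @param out optional path; when given, the report is written there as
#'   JSON (deterministically, so identical configs give byte-identical
#'   files).
#' @return the report, a nested list of class `"hostguest_report"` with
#'   sections `pocket`, `logp`, `binding`, `permeability` and `config`.
#' @examples
#' \donttest{
#' dir <- tempfile(); spec <- synthetic_spec(seed = 7)
#' paths <- write_synthetic_bundle(spec, dir)
#' rep <- run_profile(list(host = paths[["host"]],
#'                         guest = paths[["guest"]],
#'                         fragment_table = paths[["fragments"]],
#'                         pose_table = paths[["poses"]],
#'                         timecourse = paths[["timecourse"]],
#'                         c0 = 1e5,
#'                         pocket = list(center = c(0, 0, 0), radius = 2.5,
#'                                       spacing = 1)))
#' rep$pocket$site_class
#' }
#' @export
run_profile <- function(config = run_config(), out = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- run_config(config)
  weight <- distance_weight(config$weight$form, config$weight$cutoff)
  calib <- logp_calibration(config$calibration$w_plus,
                            config$calibration$w_minus,
                            config$calibration$intercept)
  fs <- .stage("chem_structures", {
    if (is.null(config$fragment_table)) default_fragment_system()
    else read_fragment_table(config$fragment_table)
  })

  host <- guest <- NULL
  pocket_sec <- logp_sec <- NULL
  if (!is.null(config$host)) {
    host <- .stage("chem_structures", read_structure(config$host,
                                                     mode = "lenient"))
    pk <- pocket_definition(config$pocket$center, config$pocket$radius,
                            config$pocket$spacing)
    prof <- .stage("pocket_profile",
                   pocket_profile(host, fs, pk, weight, mode = "lenient"))
    pocket_sec <- list(li_percent = prof$li_percent,
                       sum_plus = prof$sum_plus,
                       sum_minus = prof$sum_minus,
                       n_points = prof$n_points,
                       site_class = prof$site_class)
    host_field <- .stage("mlp_field", mlp_at_points(
      surface_points(host, config$probe_radius, config$points_per_atom),
      host, fs, weight, mode = "lenient"))
    logp_sec <- list(host = logp_mlp(host_field, calib))
  }
  if (!is.null(config$guest)) {
    guest <- .stage("chem_structures", read_structure(config$guest,
                                                      mode = "lenient"))
    guest_field <- .stage("mlp_field", mlp_at_points(
      surface_points(guest, config$probe_radius, config$points_per_atom),
      guest, fs, weight, mode = "lenient"))
    logp_sec <- c(logp_sec, list(guest = logp_mlp(guest_field, calib)))
  }

  binding_sec <- NULL
  if (!is.null(config$pose_table)) {
    binding_sec <- .stage("binding_affinity", {
      poses <- read_pose_table(config$pose_table)
      unclass(summarize_top_poses(poses, k = config$top_k,
                                  temperature = config$temperature))
    })
  }

  perm_sec <- NULL
  if (!is.null(config$timecourse)) {
    perm_sec <- .stage("transwell_permeability", {
      if (is.null(config$c0))
        stop("c0 (initial apical concentration) is required")
      geom <- transwell_geometry(config$geometry$area,
                                 config$geometry$v_basolateral,
                                 config$geometry$v_apical,
                                 config$geometry$v_sample)
      tc <- read_time_course(config$timecourse, config$c0)
      fit <- papp_fit(tc, geom, slope_mode = config$slope_mode,
                      correct_sampling = config$correct_sampling,
                      max_time_min = config$max_time_min)
      list(papp_cm_s = fit$papp, slope = fit$slope,
           coefficients = as.list(fit$coefficients),
           n_points_used = fit$n_points_used,
           permeation_class = fit$permeation_class)
    })
  }

  report <- structure(list(schema = "hostguest-report/1",
                           pocket = pocket_sec,
                           logp = logp_sec,
                           binding = binding_sec,
                           permeability = perm_sec,
                           config = .serializable_config(config)),
                      class = "hostguest_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null",
                         na = "string")
    return(invisible(report))
  }
  report
}

.serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$max_time_min <- if (is.finite(cfg$max_time_min))
    cfg$max_time_min else "Inf"
  cfg
}

#' @export
print.hostguest_report <- function(x, ...) {
  cat("Host-guest profile report\n")
  if (!is.null(x$pocket))
    cat(sprintf("  pocket      : LI %.2f%% -> %s (%d points)\n",
                x$pocket$li_percent, x$pocket$site_class,
                x$pocket$n_points))
  if (!is.null(x$logp$host))
    cat(sprintf("  logP_MLP    : host %.3f%s\n", x$logp$host,
                if (!is.null(x$logp$guest))
                  sprintf(", guest %.3f", x$logp$guest) else ""))
  if (!is.null(x$binding))
    cat(sprintf("  binding     : dG %.3f +/- %.3f kcal/mol, K %.2f mM (%s)\n",
                x$binding$mean_dg, x$binding$sd_dg, x$binding$mean_k_mM,
                x$binding$affinity_class))
  if (!is.null(x$permeability))
    cat(sprintf("  permeability: Papp %.3g cm/s (%s)\n",
                x$permeability$papp_cm_s,
                x$permeability$permeation_class))
  invisible(x)
}
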