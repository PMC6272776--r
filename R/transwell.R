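# Transwell apparent-permeability analysis:
#   Papp = (dQ/dt) * Vb / (A * C0)
# with dQ/dt the initial slope of the cumulative basolateral
# concentration, corrected for periodic sampling with medium replacement.

#' Transwell chamber geometry
#'
#' @param area diffusion (filter) area, cm^2; default 0.336.
#' @param v_basolateral basolateral chamber volume, mL; default 0.9.
#' @param v_apical apical chamber volume, mL; default 0.3.
#' @param v_sample drawn aliquot volume, mL; default 0.1 (100 uL samples
#'   replaced with fresh medium).
#' @return An object of class `"transwell_geometry"`.
#' @export
transwell_geometry <- function(area = 0.336, v_basolateral = 0.9,
                               v_apical = 0.3, v_sample = 0.1) {
  v <- c(area, v_basolateral, v_apical, v_sample)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all geometry values must be positive")
  if (v_sample >= v_basolateral)
    stop("v_sample must be smaller than v_basolateral")
  structure(list(area = area, v_basolateral = v_basolateral,
                 v_apical = v_apical, v_sample = v_sample),
            class = "transwell_geometry")
}

#' Transwell time-course
#'
#' Concentrations measured in each aliquot drawn from the basolateral
#' chamber, and the initial apical (donor) concentration.
#'
#' @param times_min sampling times, minutes, strictly increasing,
#'   length >= 2.
#' @param conc measured basolateral concentrations, ug/mL, one per time.
#' @param c0_apical initial apical concentration, ug/mL (> 0).
#' @return An object of class `"time_course"`.
#' @export
time_course <- function(times_min, conc, c0_apical) {
  if (length(times_min) != length(conc) || length(times_min) < 2L)
    stop("times and concentrations must have equal length >= 2")
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  if (!is.finite(c0_apical) || c0_apical <= 0) stop("c0_apical must be > 0")
  structure(list(times_min = as.numeric(times_min),
                 conc = as.numeric(conc),
                 c0_apical = c0_apical),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("Transwell time-course:", length(x$times_min), "samples,",
      "t =", paste(x$times_min, collapse = ", "), "min;",
      "C0(apical) =", x$c0_apical, "ug/mL\n")
  invisible(x)
}

#' Read / write a time-course CSV
#'
#' Two columns: `time_min`, `conc_ug_per_ml`. The apical concentration is
#' supplied separately (it is a protocol constant, not a measurement).
#'
#' @param path CSV path.
#' @param c0_apical initial apical concentration, ug/mL.
#' @return A [time_course()].
#' @export
read_time_course <- function(path, c0_apical) {
  df <- read.table(path, header = TRUE, sep = ",")
  if (!all(c("time_min", "conc_ug_per_ml") %in% names(df)))
    stop("time-course CSV needs columns time_min, conc_ug_per_ml")
  time_course(df$time_min, df$conc_ug_per_ml, c0_apical)
}

#' @rdname read_time_course
#' @param tc a [time_course()].
#' @export
write_time_course <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  writeLines(c("time_min,conc_ug_per_ml",
               paste(format(tc$times_min, digits = 15, trim = TRUE),
                     format(tc$conc, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     sep = ",")), path)
  invisible(path)
}

#' Cumulative transported amounts with sampling correction
#'
#' Each 100 uL aliquot removes mass that later samples no longer see; the
#' cumulative transported amount at draw i restores it:
#' `Q_i = Vb * C_i + Vs * sum_(j<i) C_j` (amount present plus amounts
#' previously removed). With `correct_sampling = FALSE` the removed-mass
#' term is dropped.
#'
#' @param tc a [time_course()].
#' @param geom a [transwell_geometry()].
#' @param correct_sampling apply the replacement correction (default
#'   `TRUE`).
#' @return cumulative amounts, ug, one per sampling time.
#' @export
cumulative_amounts <- function(tc, geom = transwell_geometry(),
                               correct_sampling = TRUE) {
  stopifnot(inherits(tc, "time_course"), inherits(geom, "transwell_geometry"))
  removed <- if (correct_sampling)
    geom$v_sample * c(0, cumsum(tc$conc)[-length(tc$conc)])
  else 0
  geom$v_basolateral * tc$conc + removed
}

#' Least-squares quadratic fit of a cumulative course
#'
#' Fits `Q(t) = a + b t + c t^2` with t in seconds. With exactly two
#' points a line is fitted (c = 0).
#'
#' @param times_min sampling times, minutes.
#' @param q cumulative concentrations (or amounts), same length.
#' @return named coefficient vector `c(a = , b = , c = )`; b is per
#'   second, c per second squared.
#' @export
fit_cumulative <- function(times_min, q) {
  if (length(times_min) != length(q) || length(times_min) < 2L)
    stop("need at least 2 points")
  t_s <- times_min * 60
  if (length(q) == 2L) {
    b <- diff(q) / diff(t_s)
    return(c(a = q[1] - b * t_s[1], b = unname(b), c = 0))
  }
  co <- coef(lm(q ~ t_s + I(t_s^2)))
  c(a = unname(co[1]), b = unname(co[2]), c = unname(co[3]))
}

#' Initial slope of a fitted cumulative course
#'
#' Either the derivative of the quadratic fit at t = 0 (its linear
#' coefficient) or the slope of a straight-line fit through the first k
#' points — provided because "initial" can reasonably mean either.
#'
#' @param fit coefficient vector from [fit_cumulative()].
#' @param mode `"derivative_at_zero"` (default) or `"first_k_points"`.
#' @param times_min,q the data points (required for `"first_k_points"`).
#' @param k number of leading points for the windowed mode (default 3).
#' @return slope, per second. A negative slope (flux reversal) triggers a
#'   warning.
#' @export
initial_slope <- function(fit, mode = c("derivative_at_zero",
                                        "first_k_points"),
                          times_min = NULL, q = NULL, k = 3) {
  mode <- match.arg(mode)
  slope <- if (mode == "derivative_at_zero") {
    unname(fit[["b"]])
  } else {
    if (is.null(times_min) || is.null(q))
      stop("first_k_points mode needs times_min and q")
    k <- min(k, length(q))
    if (k < 2L) stop("first_k_points mode needs k >= 2")
    t_s <- times_min[seq_len(k)] * 60
    unname(coef(lm(q[seq_len(k)] ~ t_s))[2])
  }
  if (slope < 0) warning("negative initial slope: flux reversal")
  slope
}

#' Fit the apparent permeability of a Transwell time-course
#'
#' The estimator behind `Papp = (dQ/dt) * Vb / (A * C0)`: corrects the
#' measured basolateral concentrations for aliquot removal/replacement,
#' converts to cumulative concentration, fits a quadratic in time, takes
#' the initial slope, and scales by the chamber geometry and donor
#' concentration. Returns a model object with the usual accessor methods
#' (`coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate`,
#' `summary`).
#'
#' @param tc a [time_course()].
#' @param geom a [transwell_geometry()].
#' @param slope_mode `"derivative_at_zero"` (default) or
#'   `"first_k_points"`.
#' @param k leading-point count for `"first_k_points"`.
#' @param correct_sampling apply the aliquot-replacement correction.
#' @param max_time_min drop samples after this time (late flattening or
#'   flux reversal); default `Inf` keeps all.
#' @return An object of class `"papp_fit"`: `papp` (cm/s), `slope`
#'   (ug/mL/s), `coefficients` (a, b, c of the quadratic),
#'   `n_points_used`, `permeation_class`, plus the inputs.
#' @examples
#' geom <- transwell_geometry()
#' tc <- simulate_transwell(synthetic_spec(seed = 1), geom)
#' fit <- papp_fit(tc, geom)
#' fit
#' @export
papp_fit <- function(tc, geom = transwell_geometry(),
                     slope_mode = c("derivative_at_zero", "first_k_points"),
                     k = 3, correct_sampling = TRUE, max_time_min = Inf) {
  stopifnot(inherits(tc, "time_course"))
  slope_mode <- match.arg(slope_mode)
  keep <- tc$times_min <= max_time_min
  if (sum(keep) < 2L) stop("fewer than 2 points before max_time_min")
  tc_used <- time_course(tc$times_min[keep], tc$conc[keep], tc$c0_apical)
  q_amount <- cumulative_amounts(tc_used, geom, correct_sampling)
  q_conc <- q_amount / geom$v_basolateral      # cumulative concentration
  fit <- fit_cumulative(tc_used$times_min, q_conc)
  slope <- initial_slope(fit, slope_mode, tc_used$times_min, q_conc, k)
  papp <- slope * geom$v_basolateral / (geom$area * tc_used$c0_apical)
  structure(list(papp = papp,
                 slope = slope,
                 coefficients = fit,
                 n_points_used = sum(keep),
                 permeation_class = if (papp >= 0)
                   classify_permeability(papp) else NA_character_,
                 slope_mode = slope_mode,
                 correct_sampling = correct_sampling,
                 time_course = tc_used,
                 q_conc = q_conc,
                 geometry = geom),
            class = "papp_fit")
}

#' @export
print.papp_fit <- function(x, ...) {
  cat("Transwell apparent permeability fit\n")
  cat(sprintf("  Papp  : %.4g cm/s (%.2f x 1e-6)\n", x$papp, x$papp * 1e6))
  cat(sprintf("  class : %s\n", x$permeation_class))
  invisible(x)
}

#' @export
summary.papp_fit <- function(object, ...) {
  x <- object
  cat("Transwell apparent permeability fit\n")
  cat(sprintf("  points used    : %d (%s)\n", x$n_points_used,
              if (x$correct_sampling) "sampling-corrected" else
                "uncorrected"))
  cat(sprintf("  quadratic fit  : Q(t) = %.4g + %.4g t + %.4g t^2  (t in s)\n",
              x$coefficients[["a"]], x$coefficients[["b"]],
              x$coefficients[["c"]]))
  cat(sprintf("  initial slope  : %.4g ug/mL/s (%s)\n", x$slope,
              x$slope_mode))
  cat(sprintf("  Papp           : %.4g cm/s\n", x$papp))
  cat(sprintf("  class          : %s (low <= 1e-6 < high <= 2e-6 < ",
              x$permeation_class))
  cat("high_bioavailable)\n")
  invisible(x)
}

#' @export
coef.papp_fit <- function(object, ...) object$coefficients

#' @export
fitted.papp_fit <- function(object, ...) {
  co <- object$coefficients
  t_s <- object$time_course$times_min * 60
  co[["a"]] + co[["b"]] * t_s + co[["c"]] * t_s^2
}

#' @export
residuals.papp_fit <- function(object, ...)
  object$q_conc - fitted(object)

#' Predict cumulative concentration at new times
#' @param object a [papp_fit()].
#' @param newdata numeric vector of times in minutes (default: the fitted
#'   times).
#' @param ... unused.
#' @return predicted cumulative basolateral concentration, ug/mL.
#' @export
predict.papp_fit <- function(object, newdata = NULL, ...) {
  t_min <- newdata %||% object$time_course$times_min
  t_s <- t_min * 60
  co <- object$coefficients
  co[["a"]] + co[["b"]] * t_s + co[["c"]] * t_s^2
}

#' @export
plot.papp_fit <- function(x, ...) {
  tmin <- x$time_course$times_min
  plot(tmin, x$q_conc, pch = 19,
       xlab = "time (min)", ylab = "cumulative concentration (ug/mL)",
       main = sprintf("Papp = %.3g cm/s (%s)", x$papp,
                      x$permeation_class), ...)
  tt <- seq(0, max(tmin), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "steelblue")
  invisible(x)
}

#' Simulate new time-courses from a fitted permeability
#'
#' Draws replicate Transwell courses at the fitted Papp using the
#' sink-condition generator, with multiplicative measurement noise.
#'
#' @param object a [papp_fit()].
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param noise_sd multiplicative noise sd (fraction; default 0.05).
#' @param ... unused.
#' @return list of [time_course()] objects.
#' @export
simulate.papp_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sd = 0.05, ...) {
  seeds <- if (is.null(seed)) sample.int(1e6, nsim) else seed + seq_len(nsim) - 1
  lapply(seeds, function(s) {
    spec <- synthetic_spec(
      seed = s,
      transwell = list(papp_true = max(object$papp, 0),
                       c0 = object$time_course$c0_apical,
                       times_min = object$time_course$times_min,
                       noise_sd = noise_sd, model = "sink_linear"))
    simulate_transwell(spec, object$geometry)
  })
}

#' Classify apparent permeability
#'
#' Permeability at or below 1e-6 cm/s is low; above 1e-6 marks high
#' absorption/permeation potential; above 2e-6 additionally indicates
#' over 90 percent bioavailability.
#'
#' @param papp apparent permeability, cm/s (>= 0).
#' @param thresholds length-2 vector, cm/s (defaults `c(1e-6, 2e-6)`).
#' @return `"low"`, `"high"` or `"high_bioavailable"`.
#' @export
classify_permeability <- function(papp, thresholds = c(1e-6, 2e-6)) {
  if (!is.finite(papp) || papp < 0)
    stop("papp must be finite and >= 0")
  if (papp <= thresholds[1]) "low"
  else if (papp <= thresholds[2]) "high"
  else "high_bioavailable"
}

#' Drug-to-complex dose equivalence
#'
#' Converts a free-drug concentration to the equivalent concentration of
#' an inclusion complex with the given drug mass fraction (loading), e.g.
#' 40 ug/mL of drug at 8.6 w% loading corresponds to about 465 ug/mL of
#' complex.
#'
#' @param drug_conc free-drug concentration, ug/mL.
#' @param drug_mass_fraction drug mass fraction of the complex, in (0, 1].
#' @return complex concentration, ug/mL.
#' @export
dose_equivalent <- function(drug_conc, drug_mass_fraction) {
  if (!is.finite(drug_mass_fraction) || drug_mass_fraction <= 0 ||
      drug_mass_fraction > 1)
    stop("drug_mass_fraction must lie in (0, 1]")
  drug_conc / drug_mass_fraction
}
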