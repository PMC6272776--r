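# Seeded synthetic-data generators: cage-like hosts with a cavity of
# tunable polarity, Transwell time-courses sampled with medium
# replacement, and docking-pose ensembles with normal energies.

#' Parameters for the synthetic-data generators
#'
#' One record fixing every generator input, so a seed reproduces all
#' synthetic data byte-for-byte. Defaults mirror the assay conditions the
#' workflow targets: 100 uL aliquots at 5, 15, 30, 60 and
#' 120 min from a 0.9 mL basolateral chamber, a donor concentration of
#' 1e5 ug/mL (100 mg/mL of complex), a true permeability of 12.32e-6
#' cm/s, 5 percent multiplicative measurement noise, and docking energies
#' centred on -1.727 kcal/mol (sd 0.042) over 100 genetic-algorithm runs.
#'
#' @param seed integer seed fixing all randomness.
#' @param cage list: `n_atoms` (>= 4, per ring), `ring_radius` (Angstrom),
#'   `interior_constant`, `exterior_constant` (lipophilic constants of the
#'   inner / outer ring).
#' @param transwell list: `papp_true` (cm/s), `c0` (ug/mL), `times_min`,
#'   `noise_sd` (fraction), `model` (`"sink_linear"` or
#'   `"two_compartment"`).
#' @param poses list: `mean_dg`, `sd_dg` (kcal/mol), `n`,
#'   `coordinate_jitter` (Angstrom).
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L,
                           cage = list(),
                           transwell = list(),
                           poses = list()) {
  cage <- utils::modifyList(
    list(n_atoms = 8L, ring_radius = 6, interior_constant = -1,
         exterior_constant = -1), cage)
  transwell <- utils::modifyList(
    list(papp_true = 12.32e-6, c0 = 1e5,
         times_min = c(5, 15, 30, 60, 120), noise_sd = 0.05,
         model = "sink_linear"), transwell)
  poses <- utils::modifyList(
    list(mean_dg = -1.727, sd_dg = 0.042, n = 100L,
         coordinate_jitter = 0.5), poses)
  if (cage$n_atoms < 4L) stop("cage needs n_atoms >= 4")
  if (transwell$noise_sd < 0) stop("noise_sd must be >= 0")
  if (transwell$papp_true < 0) stop("papp_true must be >= 0")
  if (!transwell$model %in% c("sink_linear", "two_compartment"))
    stop("unknown transwell model: ", transwell$model)
  if (poses$n < 1L || poses$sd_dg < 0)
    stop("poses need n >= 1 and sd_dg >= 0")
  structure(list(seed = as.integer(seed), cage = cage,
                 transwell = transwell, poses = poses),
            class = "synthetic_spec")
}

# run fn with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Synthetic cage-like host molecule
#'
#' A torus-like amphiphile stand-in: two concentric rings of pseudo-atoms
#' in the xy plane, the inner ring at `ring_radius` carrying the interior
#' lipophilic constant and the outer ring (2.5 Angstrom further out,
#' rotated half a step) the exterior constant. The central cavity of
#' radius `ring_radius / 2` is atom-free, so a pocket grid there probes
#' the field the ring atoms project into the cavity. The construction is
#' deterministic; the companion fragment system is attached as attribute
#' `"fragment_system"` (see [cage_fragment_system()]).
#'
#' @param spec a [synthetic_spec()].
#' @return A [molecule()] with fragment types `cage_interior` /
#'   `cage_exterior`.
#' @export
make_cage_host <- function(spec = synthetic_spec()) {
  cg <- spec$cage
  if (cg$ring_radius < 2 * 1.5)
    stop("ring_radius too small for an atom-free cavity")
  ang_in <- 2 * pi * (seq_len(cg$n_atoms) - 1) / cg$n_atoms
  ang_out <- ang_in + pi / cg$n_atoms
  r_out <- cg$ring_radius + 2.5
  atoms <- data.frame(
    element = "C",
    x = c(cg$ring_radius * cos(ang_in), r_out * cos(ang_out)),
    y = c(cg$ring_radius * sin(ang_in), r_out * sin(ang_out)),
    z = 0,
    vdw_radius = 1.5,
    fragment_type = rep(c("cage_interior", "cage_exterior"),
                        each = cg$n_atoms))
  mol <- molecule(atoms, name = sprintf("cage host (n=%d, r=%g A)",
                                        cg$n_atoms, cg$ring_radius))
  attr(mol, "fragment_system") <- cage_fragment_system(spec)
  mol
}

#' @rdname make_cage_host
#' @return `cage_fragment_system()`: the [fragment_system()] carrying the
#'   cage's interior and exterior constants.
#' @export
cage_fragment_system <- function(spec = synthetic_spec()) {
  fragment_system(c(cage_interior = spec$cage$interior_constant,
                    cage_exterior = spec$cage$exterior_constant),
                  name = "synthetic cage")
}

#' Pocket definition for a synthetic cage's cavity
#'
#' Centred at the origin with radius just inside the atom-free cavity
#' (`ring_radius / 2 - 0.5`).
#'
#' @param spec a [synthetic_spec()].
#' @param spacing grid pitch, Angstrom.
#' @return A [pocket_definition()].
#' @export
cage_pocket <- function(spec = synthetic_spec(), spacing = 1) {
  pocket_definition(c(0, 0, 0),
                    radius = max(spec$cage$ring_radius / 2 - 0.5, spacing),
                    spacing = spacing)
}

#' Simulate a Transwell time-course
#'
#' Generates the basolateral concentrations an analyst would measure in
#' each drawn aliquot, honouring the sampling protocol: at every sampling
#' time an aliquot (`v_sample`) is removed and replaced with drug-free
#' medium, so later samples see the depleted chamber.
#'
#' Transported-amount models:
#' \describe{
#'   \item{`sink_linear`}{`amount(t) = Papp * A * C0 * t` — strict sink
#'     conditions, constant flux.}
#'   \item{`two_compartment`}{`amount(t) = Q_eq (1 - exp(-k t))` with
#'     `k = Papp * A * (1/Va + 1/Vb)` and
#'     `Q_eq = C0 * Va * Vb / (Va + Vb)` — donor depletion flattens the
#'     course, emulating the early steady state seen for the complex.}
#' }
#' Multiplicative Gaussian noise of fractional sd `noise_sd` is applied to
#' each measured concentration (LC-MS/MS-like, concentration-proportional
#' error). With `censor_lloq`, values below 2.5 ug/mL are reported as 0.
#'
#' @param spec a [synthetic_spec()]; `spec$transwell` holds the model
#'   parameters and `spec$seed` the RNG seed.
#' @param geom a [transwell_geometry()].
#' @param censor_lloq censor concentrations below the 2.5 ug/mL lower
#'   limit of quantification to 0 (default `FALSE`).
#' @return A [time_course()].
#' @export
simulate_transwell <- function(spec = synthetic_spec(),
                               geom = transwell_geometry(),
                               censor_lloq = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tw <- spec$transwell
  t_s <- tw$times_min * 60
  amount <- switch(tw$model,
    sink_linear = tw$papp_true * geom$area * tw$c0 * t_s,
    two_compartment = {
      k <- tw$papp_true * geom$area *
        (1 / geom$v_apical + 1 / geom$v_basolateral)
      q_eq <- tw$c0 * geom$v_apical * geom$v_basolateral /
        (geom$v_apical + geom$v_basolateral)
      if (k == 0) rep(0, length(t_s)) else q_eq * (1 - exp(-k * t_s))
    })
  conc <- numeric(length(t_s))
  removed <- 0
  for (i in seq_along(t_s)) {
    conc[i] <- (amount[i] - removed) / geom$v_basolateral
    removed <- removed + geom$v_sample * conc[i]
  }
  if (tw$noise_sd > 0)
    conc <- .with_seed(spec$seed, function()
      conc * (1 + rnorm(length(conc), 0, tw$noise_sd)))
  conc <- pmax(conc, 0)
  if (censor_lloq) conc[conc < 2.5] <- 0
  time_course(tw$times_min, conc, tw$c0)
}

#' Simulate a docking-pose ensemble
#'
#' Energies are drawn from Normal(`mean_dg`, `sd_dg`); coordinates are a
#' fixed small guest template displaced per pose by isotropic Gaussian
#' jitter of scale `coordinate_jitter`, all under `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [pose()] objects (class `"pose_ensemble"`).
#' @export
make_pose_ensemble <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ps <- spec$poses
  template <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-0.7, 1.2, 0),
                    c(-0.7, -1.2, 0), c(0, 0, 1.4))
  .with_seed(spec$seed, function() {
    dg <- rnorm(ps$n, ps$mean_dg, ps$sd_dg)
    poses <- lapply(seq_len(ps$n), function(i) {
      jit <- matrix(rnorm(length(template), 0, ps$coordinate_jitter),
                    ncol = 3)
      pose(dg[i], template + jit, label = sprintf("pose_%03d", i))
    })
    structure(poses, class = c("pose_ensemble", "list"))
  })
}

#' Write a full synthetic input bundle
#'
#' Writes the standard files the analysis consumes: the host structure
#' (`host.xyz`), the guest template (`guest.xyz`), the cage fragment table
#' (`fragments.tsv`), a docking pose table (`poses.csv`) and a Transwell
#' time-course (`timecourse.csv`). Outputs are byte-identical for a fixed
#' spec.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param geom a [transwell_geometry()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(spec = synthetic_spec(), dir,
                                   geom = transwell_geometry()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  host <- make_cage_host(spec)
  paths <- c(host = file.path(dir, "host.xyz"),
             guest = file.path(dir, "guest.xyz"),
             fragments = file.path(dir, "fragments.tsv"),
             poses = file.path(dir, "poses.csv"),
             timecourse = file.path(dir, "timecourse.csv"))
  .write_xyz(host, paths[["host"]])
  guest <- make_pose_ensemble(synthetic_spec(seed = spec$seed,
                                             poses = list(n = 1L,
                                                          sd_dg = 0,
                                                          coordinate_jitter = 0)))[[1]]
  gm <- molecule(data.frame(element = "C", x = guest$coordinates[, 1],
                            y = guest$coordinates[, 2],
                            z = guest$coordinates[, 3]),
                 name = "guest template")
  .write_xyz(gm, paths[["guest"]])
  fs <- cage_fragment_system(spec)
  writeLines(c("# synthetic cage fragment constants",
               paste(names(fs$constants),
                     format(fs$constants, digits = 15, trim = TRUE),
                     sep = "\t"),
               paste("C", format(spec$cage$interior_constant, digits = 15,
                                 trim = TRUE), sep = "\t")),
             paths[["fragments"]])
  write_pose_table(make_pose_ensemble(spec), paths[["poses"]])
  write_time_course(simulate_transwell(spec, geom), paths[["timecourse"]])
  invisible(paths)
}

.write_xyz <- function(mol, path) {
  xyz <- coords(mol)
  writeLines(c(as.character(n_atoms(mol)),
               mol$name,
               paste(mol$atoms$element,
                     format(xyz[, 1], digits = 15, trim = TRUE),
                     format(xyz[, 2], digits = 15, trim = TRUE),
                     format(xyz[, 3], digits = 15, trim = TRUE))),
             path)
  invisible(path)
}
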