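# Docking-pose post-processing: RMSD clustering, top-pose summaries, and
# the Gibbs free energy <-> dissociation-constant conversion.

# Gas constant, kcal / (mol K)
.R_KCAL <- 1.9872e-3

#' Construct a docking pose
#'
#' @param delta_g estimated Gibbs free energy of binding, kcal/mol.
#' @param coordinates optional n x 3 matrix of guest-atom coordinates
#'   (Angstrom) in the shared receptor frame; atom ordering must be
#'   consistent across poses of one ensemble.
#' @param label pose label.
#' @return An object of class `"pose"`.
#' @export
pose <- function(delta_g, coordinates = NULL, label = "") {
  if (!is.finite(delta_g)) stop("delta_g must be finite")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (ncol(coordinates) != 3 || any(!is.finite(coordinates)))
      stop("coordinates must be a finite n x 3 matrix")
  }
  structure(list(label = label, delta_g = delta_g,
                 coordinates = coordinates), class = "pose")
}

.pose_energies <- function(poses)
  vapply(poses, function(p) p$delta_g, numeric(1))

.check_ensemble <- function(poses) {
  if (length(poses) < 1L) stop("need at least one pose")
  if (!all(vapply(poses, inherits, TRUE, "pose")))
    stop("all elements must be pose objects")
  nc <- vapply(poses, function(p)
    if (is.null(p$coordinates)) NA_integer_ else nrow(p$coordinates), 1L)
  if (length(unique(nc[!is.na(nc)])) > 1L)
    stop("format error: poses have inconsistent atom counts")
  invisible(poses)
}

#' Read a docking pose table
#'
#' CSV with header `label, delta_g` followed by optional coordinate
#' columns `x1, y1, z1, x2, ...` (one triple per guest atom, identical
#' layout on every row). Poses are returned in file order.
#'
#' @param path CSV path.
#' @return list of [pose()] objects (class `"pose_ensemble"`).
#' @export
read_pose_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("label", "delta_g") %in% names(df)))
    stop("pose table needs columns label, delta_g")
  dg <- suppressWarnings(as.numeric(df$delta_g))
  if (anyNA(dg))
    stop("parse error: non-numeric delta_g at row ", which(is.na(dg))[1])
  cc <- setdiff(names(df), c("label", "delta_g"))
  coord_rows <- vector("list", nrow(df))
  if (length(cc)) {
    vals <- suppressWarnings(
      matrix(as.numeric(as.matrix(df[, cc, drop = FALSE])),
             nrow = nrow(df)))
    n_ok <- rowSums(!is.na(vals))
    if (length(unique(n_ok)) > 1L)
      stop("format error: poses have inconsistent atom counts (rows ",
           paste(head(which(n_ok != n_ok[1]), 3), collapse = ", "), ")")
    if (n_ok[1] %% 3 != 0)
      stop("format error: ", n_ok[1],
           " coordinate values per row (not a multiple of 3)")
    if (n_ok[1] > 0)
      coord_rows <- lapply(seq_len(nrow(df)), function(i)
        matrix(vals[i, !is.na(vals[i, ])], ncol = 3, byrow = TRUE))
  }
  poses <- lapply(seq_len(nrow(df)), function(i)
    pose(dg[i], coord_rows[[i]], label = as.character(df$label[i])))
  .check_ensemble(poses)
  structure(poses, class = c("pose_ensemble", "list"))
}

#' Write a docking pose table
#'
#' @param poses list of [pose()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(poses, path) {
  .check_ensemble(poses)
  n_at <- if (is.null(poses[[1]]$coordinates)) 0L else
    nrow(poses[[1]]$coordinates)
  header <- c("label", "delta_g",
              if (n_at > 0)
                as.vector(vapply(seq_len(n_at),
                                 function(i) paste0(c("x", "y", "z"), i),
                                 character(3))))
  rows <- vapply(poses, function(p) {
    vals <- if (n_at > 0) as.vector(t(p$coordinates)) else numeric(0)
    paste(c(p$label, format(c(p$delta_g, vals), digits = 15, trim = TRUE,
                            scientific = FALSE)), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' RMSD between two poses
#'
#' Root mean squared per-atom distance in the shared receptor frame, with
#' no superposition: docked poses already live in one coordinate system,
#' and aligning them would hide the translational diversity the clustering
#' threshold is meant to capture.
#'
#' @param a,b [pose()] objects with equal atom counts.
#' @return RMSD, Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  if (is.null(a$coordinates) || is.null(b$coordinates))
    stop("both poses need coordinates")
  if (nrow(a$coordinates) != nrow(b$coordinates))
    stop("atom-count mismatch between poses")
  sqrt(mean(rowSums((a$coordinates - b$coordinates)^2)))
}

#' Greedy energy-ordered pose clustering
#'
#' The lowest-energy unassigned pose seeds a cluster and collects every
#' unassigned pose within the RMSD threshold of the seed; this repeats
#' until all poses are assigned. Clusters are ordered by seed energy and
#' the seed is the cluster representative.
#'
#' @param poses list of [pose()] objects.
#' @param threshold RMSD threshold, Angstrom (default 2).
#' @return list of clusters, each `list(representative = index,
#'   members = indices, delta_g = seed energy)`; the index vectors refer
#'   to positions in `poses`.
#' @export
cluster_poses <- function(poses, threshold = 2.0) {
  .check_ensemble(poses)
  dg <- .pose_energies(poses)
  unassigned <- order(dg)   # stable: ties broken by input order
  clusters <- list()
  while (length(unassigned)) {
    seed <- unassigned[1]
    rm <- vapply(unassigned, function(i)
      pose_rmsd(poses[[seed]], poses[[i]]), numeric(1))
    members <- unassigned[rm <= threshold]
    clusters[[length(clusters) + 1L]] <-
      list(representative = seed, members = members, delta_g = dg[seed])
    unassigned <- setdiff(unassigned, members)
  }
  clusters
}

#' Convert binding free energy to a dissociation-scale constant
#'
#' `K = exp(dG / (R T))` with R = 1.9872e-3 kcal/(mol K). On this
#' dissociation scale a weak binder (dG near zero) has K near 1 M and
#' millimolar K signals rapid guest liberation; it is the convention under
#' which a docking energy of about -1.7 kcal/mol corresponds to tens of
#' millimolar.
#'
#' @param delta_g Gibbs free energy of binding, kcal/mol (vectorised).
#' @param temperature absolute temperature, K (default 298.15).
#' @return equilibrium constant, molar.
#' @export
delta_g_to_k <- function(delta_g, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive")
  exp(delta_g / (.R_KCAL * temperature))
}

#' @rdname delta_g_to_k
#' @param k equilibrium constant, molar; must be positive.
#' @return `k_to_delta_g()`: Gibbs free energy, kcal/mol.
#' @export
k_to_delta_g <- function(k, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive")
  if (any(k <= 0)) stop("domain error: k must be positive")
  .R_KCAL * temperature * log(k)
}

#' Summarise the top docking poses
#'
#' Takes the k lowest-energy poses (optionally after RMSD clustering, in
#' which case cluster representatives are ranked), reports mean and sample
#' standard deviation of the binding energy, and converts each selected
#' pose's energy to a dissociation-scale constant before averaging those.
#'
#' @param poses list of [pose()] objects.
#' @param k number of top poses (default 3); if it exceeds the pose count,
#'   all poses are used with a warning.
#' @param temperature K (default 298.15).
#' @param cluster if `TRUE`, rank cluster representatives instead of raw
#'   poses.
#' @param threshold RMSD clustering threshold, Angstrom.
#' @return An object of class `"binding_summary"`: `n_poses`, `mean_dg`,
#'   `sd_dg` (kcal/mol), `mean_k_mM`, `sd_k_mM`, `temperature_K`,
#'   `affinity_class`.
#' @export
summarize_top_poses <- function(poses, k = 3, temperature = 298.15,
                                cluster = FALSE, threshold = 2.0) {
  .check_ensemble(poses)
  if (k < 1) stop("k must be >= 1")
  dg <- if (cluster)
    vapply(cluster_poses(poses, threshold), `[[`, numeric(1), "delta_g")
  else .pose_energies(poses)
  if (k > length(dg)) {
    warning("k = ", k, " exceeds the ", length(dg),
            " available poses; using all")
    k <- length(dg)
  }
  top <- sort(dg)[seq_len(k)]
  kvals <- delta_g_to_k(top, temperature) * 1000   # molar -> mM
  structure(list(n_poses = k,
                 mean_dg = mean(top),
                 sd_dg = if (k > 1) sd(top) else 0,
                 mean_k_mM = mean(kvals),
                 sd_k_mM = if (k > 1) sd(kvals) else 0,
                 temperature_K = temperature,
                 affinity_class = classify_affinity(mean(top))),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat("Binding summary (", x$n_poses, " top poses, T = ",
      x$temperature_K, " K)\n", sep = "")
  cat(sprintf("  dG_bind : %.3f +/- %.3f kcal/mol\n", x$mean_dg, x$sd_dg))
  cat(sprintf("  K       : %.2f +/- %.2f mM\n", x$mean_k_mM, x$sd_k_mM))
  cat(sprintf("  affinity: %s (high iff dG <= -6.0 kcal/mol)\n",
              x$affinity_class))
  invisible(x)
}

#' Serialise a binding summary to JSON
#'
#' @param x a binding summary from [summarize_top_poses()].
#' @param path optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
binding_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "binding_summary"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Classify binding affinity
#'
#' High affinity when the binding free energy is at or below
#' -6.0 kcal/mol; otherwise low.
#'
#' @param delta_g kcal/mol.
#' @param threshold affinity threshold, kcal/mol (default -6.0).
#' @return `"high"` or `"low"`.
#' @export
classify_affinity <- function(delta_g, threshold = -6.0) {
  if (!is.finite(delta_g)) stop("delta_g must be finite")
  if (delta_g <= threshold) "high" else "low"
}
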