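# Solvent-accessible surface point sampling (Shrake-Rupley style):
# deterministic golden-spiral sampling of each atom's probe-expanded
# sphere, discarding points buried inside any other expanded sphere.

# Golden-spiral unit sphere: n deterministic, near-uniform directions in a
# fixed order.
.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Canonical molecule-fixed frame so that sampled surface points co-rotate
# with the molecule: principal axes of the coordinate spread, signs fixed
# by the third moment along each axis, right-handed. Falls back to the lab
# frame when the geometry is too degenerate to orient (single atoms,
# high-symmetry molecules) - still deterministic, just not
# rotation-covariant.
.molecule_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3L) return(diag(3))
  ctr <- colMeans(xyz)
  d <- sweep(xyz, 2, ctr)
  cv <- crossprod(d) / n
  ev <- eigen(cv, symmetric = TRUE)
  if (min(diff(rev(ev$values))) < 1e-8 * max(ev$values, 1e-12)) return(diag(3))
  v <- ev$vectors
  for (k in 1:2) {
    s <- sum((d %*% v[, k])^3)
    if (abs(s) < 1e-8) return(diag(3))
    if (s < 0) v[, k] <- -v[, k]
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  v
}

#' Sample points on the solvent-accessible surface
#'
#' Deterministic Shrake-Rupley-style sampling: each atom's van der Waals
#' sphere is inflated by the probe radius and covered with a golden-spiral
#' point set; a point survives if it lies at or beyond every other atom's
#' inflated sphere. Sampling directions are expressed in a canonical
#' molecule-fixed frame, so for molecules of generic shape the point set
#' co-translates and co-rotates with the molecule.
#'
#' Points touching another sphere exactly are kept only for the
#' lowest-index atom, so coincident duplicate atoms contribute a single
#' sphere's point set.
#'
#' @param mol a [molecule()].
#' @param probe_radius probe sphere radius, Angstrom (default 1.4, water).
#' @param points_per_atom sphere sample size per atom (>= 1).
#' @return numeric matrix of surviving points (columns x, y, z, Angstrom)
#'   with an `atom` attribute giving each point's parent atom index.
#' @examples
#' m <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
#' p <- surface_points(m, probe_radius = 1.4, points_per_atom = 50)
#' range(sqrt(rowSums(p^2)))  # all at 1.7 + 1.4
#' @export
surface_points <- function(mol, probe_radius = 1.4, points_per_atom = 100L) {
  stopifnot(inherits(mol, "molecule"))
  if (points_per_atom < 1L) stop("points_per_atom must be >= 1")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  xyz <- coords(mol)
  n <- nrow(xyz)
  rad <- mol$atoms$vdw_radius + probe_radius
  dirs <- .golden_spiral(as.integer(points_per_atom)) %*%
    t(.molecule_frame(xyz))
  tol <- 1e-9
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * rad[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)[-i]) {
      dj <- sqrt(rowSums(sweep(pts, 2, xyz[j, ])^2))
      buried <- dj < rad[j] - tol | (dj <= rad[j] + tol & j < i)
      keep <- keep & !buried
      if (!any(keep)) break
    }
    out[[i]] <- pts[keep, , drop = FALSE]
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "atom") <- rep(seq_len(n), vapply(out, nrow, 1L))
  pts
}
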