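#' Define a spherical binding pocket
#'
#' A pocket is a sphere in the receptor frame in which cavity fitting
#' points are laid out on a cubic grid. The default center is the docking
#' box center used for the cyclodextrin cavity; supply your own for other
#' systems.
#'
#' @param center length-3 pocket center, Angstrom.
#' @param radius sphere radius, Angstrom.
#' @param spacing cubic grid pitch, Angstrom; must satisfy
#'   `radius >= spacing > 0`.
#' @return An object of class `"pocket_definition"`.
#' @export
pocket_definition <- function(center = c(56.49, 12.97, 9.29), radius = 5,
                              spacing = 1) {
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("`center` must be a finite 3-vector")
  if (!(spacing > 0) || !(radius >= spacing))
    stop("need radius >= spacing > 0")
  structure(list(center = center, radius = radius, spacing = spacing),
            class = "pocket_definition")
}

#' Cavity fitting points for a pocket
#'
#' Lays a cubic grid (pitch `spacing`, the pocket center on a grid node)
#' over the pocket sphere and drops points inside any atom's van der Waals
#' sphere. Points are ordered by x, then y, then z.
#'
#' @param pocket a [pocket_definition()].
#' @param mol a [molecule()] whose atoms exclude grid points, or `NULL`
#'   for no exclusion.
#' @return numeric matrix (n x 3) of fitting points, Angstrom.
#' @examples
#' nrow(generate_fitting_points(pocket_definition(c(0, 0, 0), 1, 1)))  # 7
#' @export
generate_fitting_points <- function(pocket, mol = NULL) {
  stopifnot(inherits(pocket, "pocket_definition"))
  k <- floor(pocket$radius / pocket$spacing)
  off <- seq(-k, k) * pocket$spacing
  g <- as.matrix(expand.grid(x = off, y = off, z = off))
  g <- g[rowSums(g^2) <= pocket$radius^2 + 1e-12, , drop = FALSE]
  g <- sweep(g, 2, pocket$center, "+")
  if (!is.null(mol) && n_atoms(mol) > 0) {
    xyz <- coords(mol)
    rad <- mol$atoms$vdw_radius
    keep <- rep(TRUE, nrow(g))
    for (j in seq_len(nrow(xyz))) {
      keep <- keep &
        sqrt(rowSums(sweep(g, 2, xyz[j, ])^2)) >= rad[j] - 1e-12
      if (!any(keep)) break
    }
    g <- g[keep, , drop = FALSE]
  }
  if (nrow(g) == 0L)
    stop("empty pocket: no fitting points survive the van der Waals ",
         "exclusion")
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  dimnames(g) <- list(NULL, c("x", "y", "z"))
  g
}

#' Lipophilicity index of an MLP field
#'
#' `LI = |sum(MLP+)| / (|sum(MLP+)| + |sum(MLP-)|) * 100`: the percentage
#' of the field's absolute MLP carried by hydrophobic points. LI below 10
#' percent marks a polar binding site.
#'
#' @param field an [mlp_field()].
#' @return LI in percent, in \[0, 100\].
#' @export
lipophilicity_index <- function(field) {
  s <- mlp_sums(field)
  denom <- abs(s[["sum_plus"]]) + abs(s[["sum_minus"]])
  if (denom == 0)
    stop("undefined lipophilicity index: all MLP values are zero")
  unname(abs(s[["sum_plus"]]) / denom * 100)
}

#' Classify a binding site by lipophilicity index
#'
#' Polar when LI < 10 percent, non-polar otherwise (the 10 percent
#' boundary itself is non-polar, since polar sites are defined strictly
#' below the threshold).
#'
#' @param li_percent LI in \[0, 100\].
#' @param threshold polarity threshold in percent (default 10).
#' @return `"polar"` or `"non-polar"`.
#' @export
classify_site <- function(li_percent, threshold = 10) {
  if (!is.finite(li_percent) || li_percent < 0 || li_percent > 100)
    stop("LI must lie in [0, 100]")
  if (li_percent < threshold) "polar" else "non-polar"
}

#' Profile a binding pocket
#'
#' Generates cavity fitting points, evaluates the MLP field over them, and
#' scores the pocket: lipophilicity index, hydrophobic/polar sums, and the
#' polar / non-polar site class.
#'
#' @param mol a [molecule()] (the host).
#' @param fs a [fragment_system()].
#' @param pocket a [pocket_definition()].
#' @param weight a [distance_weight()].
#' @param mode constant-lookup mode.
#' @return An object of class `"pocket_profile"` with elements
#'   `li_percent`, `sum_plus`, `sum_minus`, `n_points`, `site_class` and
#'   the underlying `field`.
#' @export
pocket_profile <- function(mol, fs, pocket = pocket_definition(),
                           weight = distance_weight(),
                           mode = c("strict", "lenient")) {
  pts <- generate_fitting_points(pocket, mol)
  field <- mlp_at_points(pts, mol, fs, weight, mode)
  li <- lipophilicity_index(field)
  s <- mlp_sums(field)
  structure(list(li_percent = li,
                 sum_plus = unname(s[["sum_plus"]]),
                 sum_minus = unname(s[["sum_minus"]]),
                 n_points = nrow(pts),
                 site_class = classify_site(li),
                 field = field),
            class = "pocket_profile")
}

#' @export
print.pocket_profile <- function(x, ...) {
  cat("Pocket profile\n")
  cat(sprintf("  fitting points : %d\n", x$n_points))
  cat(sprintf("  sum(MLP+)      : %.4g\n", x$sum_plus))
  cat(sprintf("  sum(MLP-)      : %.4g\n", x$sum_minus))
  cat(sprintf("  LI             : %.2f%%\n", x$li_percent))
  cat(sprintf("  site class     : %s (polar iff LI < 10%%)\n", x$site_class))
  invisible(x)
}

#' Serialise a pocket profile to JSON
#'
#' @param x a [pocket_profile()].
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
pocket_profile_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "pocket_profile"))
  rec <- list(li_percent = x$li_percent, sum_plus = x$sum_plus,
              sum_minus = x$sum_minus, n_points = x$n_points,
              site_class = x$site_class)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
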