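#' Distance weighting function for the MLP
#'
#' The molecular lipophilicity potential at a space point k sums the
#' fragmental constants f_i of all atoms, each damped by a distance
#' function fct of the atom-point distance d_ik:
#' exponential `fct(d) = exp(-d/2)` (default) or hyperbolic
#' `fct(d) = 1/(1 + d)`, with `fct(d) = 0` beyond the cutoff.
#'
#' @param form `"exponential"` or `"hyperbolic"`.
#' @param cutoff distance cutoff, Angstrom (default 10; `Inf` disables it).
#' @return An object of class `"distance_weight"`.
#' @export
distance_weight <- function(form = c("exponential", "hyperbolic"),
                            cutoff = 10) {
  form <- match.arg(form)
  if (!is.finite(cutoff) && cutoff != Inf) stop("cutoff must be positive")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(form = form, cutoff = cutoff), class = "distance_weight")
}

.weight_eval <- function(weight, d) {
  w <- switch(weight$form,
              exponential = exp(-d / 2),
              hyperbolic = 1 / (1 + d))
  w[d > weight$cutoff] <- 0
  w
}

#' Construct an MLP field
#'
#' A set of spatial points, each carrying a molecular lipophilicity
#' potential value. Usually produced by [mlp_at_points()].
#'
#' @param points numeric matrix (n x 3), Angstrom.
#' @param values numeric vector of MLP values, length n.
#' @param source provenance text.
#' @return An object of class `"mlp_field"`.
#' @export
mlp_field <- function(points, values, source = "") {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must be an n x 3 matrix")
  if (nrow(points) != length(values))
    stop("points and values lengths differ")
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("MLP values must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, values = values, source = source),
            class = "mlp_field")
}

#' @export
print.mlp_field <- function(x, ...) {
  s <- mlp_sums(x)
  cat("MLP field:", length(x$values), "points",
      if (nzchar(x$source)) paste0("[", x$source, "]"), "\n")
  cat(sprintf("  sum(MLP+) = %.4g, sum(MLP-) = %.4g\n", s[["sum_plus"]],
              s[["sum_minus"]]))
  invisible(x)
}

#' Evaluate the molecular lipophilicity potential at points
#'
#' MLP(k) = sum_i f_i * fct(d_ik) over all N atoms, where f_i are the
#' fragmental lipophilic constants of the molecule under the fragment
#' system and fct is the distance weighting.
#'
#' @param points numeric matrix (n x 3) of query points, Angstrom.
#' @param mol a [molecule()].
#' @param fs a [fragment_system()].
#' @param weight a [distance_weight()].
#' @param mode constant-lookup mode for [assign_constants()].
#' @return An [mlp_field()] over `points`.
#' @examples
#' m <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
#' f <- mlp_at_points(rbind(c(0, 0, 2)), m, fragment_system(c(C = 0.5)))
#' f$values  # 0.5 * exp(-1)
#' @export
mlp_at_points <- function(points, mol, fs, weight = distance_weight(),
                          mode = c("strict", "lenient")) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("`points` must be non-empty")
  storage.mode(points) <- "double"
  f <- assign_constants(mol, fs, match.arg(mode))
  xyz <- coords(mol)
  # n_points x n_atoms distance matrix; fine at profiling scales
  d2 <- outer(rowSums(points^2), rowSums(xyz^2), "+") -
    2 * points %*% t(xyz)
  d <- sqrt(pmax(d2, 0))
  vals <- as.vector(.weight_eval(weight, d) %*% f)
  mlp_field(points, vals,
            source = sprintf("%s | %s, cutoff %g A", mol$name, weight$form,
                             weight$cutoff))
}

#' Hydrophobic and polar MLP sums
#'
#' Splits a field's MLP values into the hydrophobic part
#' (sum of positive values) and the polar part (sum of negative values).
#'
#' @param field an [mlp_field()].
#' @return named numeric vector `c(sum_plus = , sum_minus = )` with
#'   `sum_plus >= 0` and `sum_minus <= 0`.
#' @export
mlp_sums <- function(field) {
  stopifnot(inherits(field, "mlp_field"))
  v <- field$values
  c(sum_plus = sum(v[v > 0]), sum_minus = sum(v[v < 0]))
}

#' logP calibration weights
#'
#' Linear weights mapping the hydrophobic and polar MLP sums of a
#' molecular surface to logP:
#' `logP_MLP = sum(MLP+) * w_plus + sum(MLP-) * w_minus + intercept`.
#'
#' @param w_plus weight on the hydrophobic sum.
#' @param w_minus weight on the polar sum.
#' @param intercept additive constant C.
#' @return An object of class `"logp_calibration"`.
#' @seealso [calibrate_logp()] to fit these from training data.
#' @export
logp_calibration <- function(w_plus = 1, w_minus = 1, intercept = 0) {
  v <- c(w_plus, w_minus, intercept)
  if (length(v) != 3 || any(!is.finite(v)))
    stop("calibration parameters must be three finite numbers")
  structure(list(w_plus = w_plus, w_minus = w_minus, intercept = intercept),
            class = "logp_calibration")
}

#' @export
print.logp_calibration <- function(x, ...) {
  cat(sprintf("logP calibration: w+ = %.6g, w- = %.6g, C = %.6g\n",
              x$w_plus, x$w_minus, x$intercept))
  if (!is.null(attr(x, "sigma")))
    cat(sprintf("  residual sd %.4g on %d training records\n",
                attr(x, "sigma"), attr(x, "n_train")))
  invisible(x)
}

#' Back-calculate logP from an MLP field
#'
#' `logP_MLP = sum(MLP+) * w_plus + sum(MLP-) * w_minus + C`, where the
#' sums are taken over the field (typically a molecular surface point set).
#' With the uncalibrated default weights (1, 1, 0) the value orders
#' molecules by hydrophobicity but is not an absolute logP; calibrate with
#' [calibrate_logp()] for absolute predictions.
#'
#' @param field an [mlp_field()].
#' @param calib a [logp_calibration()]; if omitted, the uncalibrated
#'   default (1, 1, 0) is used with a warning.
#' @return logP_MLP, a single number.
#' @export
logp_mlp <- function(field, calib = NULL) {
  if (is.null(calib)) {
    warning("no calibration supplied: using (w+ = 1, w- = 1, C = 0); ",
            "absolute logP requires calibrate_logp()")
    calib <- logp_calibration()
  }
  stopifnot(inherits(calib, "logp_calibration"))
  s <- mlp_sums(field)
  unname(s[["sum_plus"]] * calib$w_plus + s[["sum_minus"]] * calib$w_minus +
           calib$intercept)
}

#' Calibrate logP weights on training fields
#'
#' Ordinary least squares of experimental logP on the hydrophobic and
#' polar MLP sums (with intercept), the standard way MLP-based logP
#' back-calculation is parameterised on molecules of known logP.
#'
#' @param fields list of [mlp_field()] training surfaces.
#' @param logp numeric vector of experimental logP values, one per field.
#' @return A [logp_calibration()] with attributes `sigma` (residual sd),
#'   `residuals` and `n_train`.
#' @export
calibrate_logp <- function(fields, logp) {
  if (length(fields) != length(logp))
    stop("fields and logp lengths differ")
  if (length(fields) < 3L)
    stop("calibration needs at least 3 training records")
  sums <- t(vapply(fields, mlp_sums, numeric(2)))
  X <- cbind(sums, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("calibration error: rank-deficient design ",
         "(training sums do not span w+, w-, C)")
  beta <- qr.coef(qrX, logp)
  res <- logp - as.vector(X %*% beta)
  out <- logp_calibration(unname(beta[1]), unname(beta[2]),
                          unname(beta[3]))
  attr(out, "sigma") <- if (length(logp) > 3)
    sqrt(sum(res^2) / (length(logp) - 3)) else 0
  attr(out, "residuals") <- res
  attr(out, "n_train") <- length(logp)
  out
}

#' Write / read an MLP field as CSV
#'
#' Four columns: x, y, z (Angstrom) and mlp.
#'
#' @param field an [mlp_field()].
#' @param path output / input CSV path.
#' @return `write_mlp_field()` returns `path` invisibly; `read_mlp_field()`
#'   returns an [mlp_field()].
#' @export
write_mlp_field <- function(field, path) {
  stopifnot(inherits(field, "mlp_field"))
  df <- data.frame(field$points, mlp = field$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mlp_field
#' @export
read_mlp_field <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  if (!all(c("x", "y", "z", "mlp") %in% names(df)))
    stop("MLP field CSV needs columns x, y, z, mlp")
  mlp_field(as.matrix(df[, c("x", "y", "z")]), df$mlp,
            source = basename(path))
}

#' Write an MLP field as a PDB-style point cloud
#'
#' One HETATM pseudo-atom per field point with the MLP value in the
#' B-factor column (clamped to the column's fixed width), for inspection
#' in molecular viewers.
#'
#' @param field an [mlp_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mlp_pdb <- function(field, path) {
  stopifnot(inherits(field, "mlp_field"))
  b <- pmax(pmin(field$values, 999.99), -99.99)
  lines <- sprintf(
    "HETATM%5d  DU  MLP A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          DU",
    seq_along(b) %% 100000, seq_along(b) %% 10000,
    field$points[, 1], field$points[, 2], field$points[, 3], 1, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
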