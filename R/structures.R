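#' Construct a molecule
#'
#' A molecule is an ordered set of heavy atoms with Cartesian coordinates
#' (Angstrom), van der Waals radii and a fragment type used to look up
#' lipophilic constants. Atom order is preserved from the input and defines
#' atom indices (1-based).
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `vdw_radius` (Angstrom) and `fragment_type`. Missing radii
#'   are filled from a packaged element table; missing fragment types
#'   default to the element symbol.
#' @param name molecule name.
#' @param bonds optional two-column integer matrix of 1-based atom index
#'   pairs.
#' @param mode `"strict"` errors on elements absent from the radius table;
#'   `"lenient"` assigns 1.7 Angstrom with a warning.
#' @return An object of class `"molecule"`.
#' @seealso [read_structure()]
#' @examples
#' m <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
#' n_atoms(m)
#' @export
molecule <- function(atoms, name = "molecule", bonds = NULL,
                     mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(atoms))
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("`atoms` must have columns element, x, y, z")
  if (nrow(atoms) < 1L) stop("a molecule needs at least 1 atom")
  atoms$element <- as.character(atoms$element)
  if (any(!nzchar(atoms$element)) || anyNA(atoms$element))
    stop("element symbols must be non-empty")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- NA_real_
  miss <- is.na(atoms$vdw_radius)
  if (any(miss)) {
    r <- .vdw_radii[atoms$element[miss]]
    unknown <- is.na(r)
    if (any(unknown)) {
      if (mode == "strict")
        stop("unknown element(s) with no van der Waals radius: ",
             paste(unique(atoms$element[miss][unknown]), collapse = ", "))
      warning("unknown element(s) ",
              paste(unique(atoms$element[miss][unknown]), collapse = ", "),
              ": using default van der Waals radius ", .default_vdw, " A")
      r[unknown] <- .default_vdw
    }
    atoms$vdw_radius[miss] <- r
  }
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0))
    stop("van der Waals radii must be positive")
  if (is.null(atoms$fragment_type)) atoms$fragment_type <- atoms$element
  atoms$fragment_type <- as.character(atoms$fragment_type)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > nrow(atoms)))
      stop("bond indices out of range")
  }
  structure(
    list(name = name,
         atoms = atoms[, c("element", "x", "y", "z", "vdw_radius",
                           "fragment_type")],
         bonds = bonds),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("Molecule:", x$name, "\n")
  cat(" ", n_atoms(x), "atoms",
      if (!is.null(x$bonds)) paste0("(", nrow(x$bonds), " bonds)"), "\n")
  cat("  elements:",
      paste(names(sort(table(x$atoms$element), decreasing = TRUE)),
            sort(table(x$atoms$element), decreasing = TRUE),
            sep = "", collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a [molecule()].
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinates as a matrix
#' @param mol a [molecule()].
#' @return numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Apply a rigid transform to a molecule
#'
#' @param mol a [molecule()].
#' @param rotation 3x3 rotation matrix (applied first).
#' @param translation length-3 shift vector, Angstrom.
#' @return the transformed molecule.
#' @export
transform_molecule <- function(mol, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  xyz <- coords(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Read a small-molecule structure file
#'
#' Supports SDF/MOL (V2000, read through ChemmineR), PDB (ATOM/HETATM
#' records, read through bio3d) and XYZ. XYZ accepts both the standard
#' layout (atom count, comment, then `element x y z` lines) and bare
#' coordinate lines. Coordinates are taken as Angstrom; van der Waals radii
#' are filled from a packaged element table.
#'
#' @param path file path.
#' @param format `"sdf"`, `"pdb"`, `"xyz"`, or `"auto"` to infer from the
#'   file extension.
#' @param mode passed to [molecule()]: `"strict"` errors on unknown
#'   elements, `"lenient"` assigns a 1.7 Angstrom default radius with a
#'   warning.
#' @return A [molecule()]; atom order follows the file.
#' @examples
#' sdf <- system.file("extdata", "sevoflurane.sdf", package = "hostguest")
#' read_structure(sdf)
#' @export
read_structure <- function(path, format = c("auto", "sdf", "pdb", "xyz"),
                           mode = c("strict", "lenient")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("parse error: empty file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = , mol = "sdf", pdb = "pdb", xyz = "xyz",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         sdf = .read_sdf(path, mode),
         pdb = .read_pdb(path, mode),
         xyz = .read_xyz(path, mode))
}

.read_sdf <- function(path, mode) {
  set <- tryCatch(ChemmineR::read.SDFset(path),
                  error = function(e) stop("parse error in SDF '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) < 1L) stop("parse error: no molecules in SDF: ", path)
  sdf <- set[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (nrow(ab) < 1L) stop("parse error: no atoms in SDF: ", path)
  elem <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (nrow(bb) > 0) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
  if (is.null(nm) || !nzchar(nm)) nm <- basename(path)
  molecule(data.frame(element = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3]),
           name = nm, bonds = bonds, mode = mode)
}

.read_pdb <- function(path, mode) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("parse error in PDB '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) < 1L) stop("parse error: no atoms in PDB: ", path)
  elem <- trimws(at$elesy)
  # fall back to the first letter(s) of the atom name when the element
  # column is blank (common in minimal PDB writers)
  blank <- !nzchar(elem) | is.na(elem)
  elem[blank] <- sub("[0-9'].*$", "", trimws(at$elety[blank]))
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, nchar(elem))))
  molecule(data.frame(element = elem, x = at$x, y = at$y, z = at$z),
           name = basename(path), mode = mode)
}

.read_xyz <- function(path, mode) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: empty XYZ file: ", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 1L && grepl("^[0-9]+$", first)) {
    n <- as.integer(first)
    body <- lines[-(1:2)]               # count line + comment line
    if (length(body) < n)
      stop("parse error: XYZ declares ", n, " atoms but has ", length(body))
    body <- body[seq_len(n)]
  } else {
    body <- lines
  }
  toks <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad))
    stop("parse error: malformed XYZ record at line ", bad[1])
  elem <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("parse error: non-numeric XYZ coordinates")
  molecule(data.frame(element = elem, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3]),
           name = basename(path), mode = mode)
}
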