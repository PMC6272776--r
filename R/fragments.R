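#' Fragment lipophilicity system
#'
#' Maps fragment types (atom-typing tokens) to fragmental lipophilic
#' constants f_i, with an optional element-level fallback used in lenient
#' lookup mode. Positive constants mark hydrophobic fragments, negative
#' constants polar ones.
#'
#' @param constants named numeric vector, fragment type -> f_i.
#' @param fallback optional named numeric vector, element -> f_i, used when
#'   a fragment type is absent and lookup is lenient.
#' @param name system name (provenance).
#' @return An object of class `"fragment_system"`.
#' @examples
#' fs <- fragment_system(c(C = 0.36, F = -0.38))
#' @export
fragment_system <- function(constants, fallback = NULL,
                            name = "fragment_system") {
  constants <- unlist(constants)
  if (length(constants) && (is.null(names(constants)) ||
                            any(!nzchar(names(constants)))))
    stop("`constants` must be a named numeric vector")
  if (length(constants) && any(!is.finite(constants)))
    stop("lipophilic constants must be finite")
  if (!is.null(fallback)) {
    fallback <- unlist(fallback)
    if (is.null(names(fallback)) || any(!is.finite(fallback)))
      stop("`fallback` must be a named finite numeric vector")
  }
  structure(list(name = name, constants = constants, fallback = fallback),
            class = "fragment_system")
}

#' @export
print.fragment_system <- function(x, ...) {
  cat("Fragment system:", x$name, "-", length(x$constants), "typed constants",
      if (length(x$fallback)) paste0("(+", length(x$fallback),
                                     " element fallbacks)"), "\n")
  invisible(x)
}

#' Read a fragment constant table
#'
#' Two-column TSV (fragment type, constant); lines starting with `#` are
#' comments. The table doubles as its own element fallback when the types
#' are element symbols.
#'
#' @param path TSV file path.
#' @param name system name; defaults to the file name.
#' @return A [fragment_system()].
#' @export
read_fragment_table <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("type", "f"),
                    colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) stop("empty fragment table: ", path)
  consts <- setNames(tab$f, tab$type)
  fragment_system(consts, fallback = consts, name = name)
}

#' Packaged element-level fragment system
#'
#' Element-level lipophilic constants for heavy atoms with hydrogen
#' contributions folded in, in the lineage of published atomic fragmental
#' systems (Broto; Ghose-Crippen). Suitable for qualitative
#' hydrophobic/polar profiling; absolute logP back-calculation additionally
#' needs [calibrate_logp()].
#'
#' @return A [fragment_system()].
#' @export
default_fragment_system <- function() {
  read_fragment_table(system.file("extdata", "default.tsv",
                                  package = "hostguest"),
                      name = "default (element-level)")
}

#' Assign lipophilic constants to atoms
#'
#' Looks each atom's `fragment_type` up in the fragment system. In strict
#' mode every type must resolve; in lenient mode unresolved types fall back
#' to the element-level table.
#'
#' @param mol a [molecule()].
#' @param fs a [fragment_system()].
#' @param mode `"strict"` or `"lenient"`.
#' @return numeric vector of f_i, one per atom, in atom order.
#' @examples
#' m <- molecule(data.frame(element = "F", x = 0, y = 0, z = 0))
#' assign_constants(m, fragment_system(c(F = -0.38)))
#' @export
assign_constants <- function(mol, fs, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mol, "molecule"), inherits(fs, "fragment_system"))
  f <- unname(fs$constants[mol$atoms$fragment_type])
  miss <- is.na(f)
  if (any(miss)) {
    if (mode == "lenient" && length(fs$fallback)) {
      fb <- unname(fs$fallback[mol$atoms$element[miss]])
      f[miss] <- fb
      miss <- is.na(f)
    }
    if (any(miss)) {
      i <- which(miss)[1]
      stop("typing error: atom ", i, " (type '",
           mol$atoms$fragment_type[i], "', element '",
           mol$atoms$element[i], "') has no lipophilic constant")
    }
  }
  f
}
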