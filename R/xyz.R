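# Molecule3D: elements + Cartesian coordinates, optional atom-map numbers and
# the SMILES the structure was matched against.

ELEMENT_NUMBERS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Br = 35, I = 53
)

#' Construct a molecule from elements and coordinates
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3), Cartesian angstroms.
#' @param map_numbers optional integer vector of per-atom atom-map numbers
#'   (positive, unique within the molecule); `NA` marks unmapped atoms.
#' @param source_smiles optional SMILES string this structure corresponds to.
#' @return object of class `molecule3d`.
#' @export
molecule3d <- function(elements, coords, map_numbers = NULL,
                       source_smiles = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(elements) == nrow(coords))
  if (!all(elements %in% names(ELEMENT_NUMBERS))) {
    stop("unknown element symbol(s): ",
         paste(setdiff(elements, names(ELEMENT_NUMBERS)), collapse = ", "))
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(map_numbers)) {
    stopifnot(length(map_numbers) == length(elements))
    mm <- map_numbers[!is.na(map_numbers)]
    if (any(mm <= 0) || anyDuplicated(mm)) {
      stop("map numbers must be positive and unique within a molecule")
    }
  }
  structure(
    list(elements = as.character(elements), coords = coords,
         map_numbers = map_numbers, source_smiles = source_smiles),
    class = "molecule3d"
  )
}

#' @export
print.molecule3d <- function(x, ...) {
  cat("<molecule3d> ", length(x$elements), " atoms: ",
      paste(x$elements, collapse = " "), "\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

#' Parse an xyz-format block
#'
#' Standard xyz: first line the atom count, second line a free-form comment,
#' then one `symbol x y z` line per atom (units angstrom).
#'
#' @param text a single string, or a character vector of lines.
#' @return a [molecule3d()].
#' @export
parse_xyz <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  if (!length(lines)) stop("empty xyz input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("first xyz line must be a positive atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("xyz header declares %d atoms but only %d atom lines follow",
                 n, length(body)))
  }
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad)) stop("malformed xyz atom line: ", body[bad[1]])
  elements <- vapply(toks, `[[`, "", 1L)
  coords <- t(vapply(toks, function(tk) {
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(is.na(xyz))) stop("unparsable coordinate in xyz line: ",
                              paste(tk, collapse = " "))
    xyz
  }, numeric(3)))
  molecule3d(elements, coords)
}

#' Read an xyz file
#'
#' @param path path to an xyz file.
#' @return a [molecule3d()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("cannot open xyz file: ", path)
  parse_xyz(readLines(path, warn = FALSE))
}

#' Write a molecule as an xyz file
#'
#' @param mol a [molecule3d()].
#' @param path output path.
#' @param comment comment line content.
#' @export
write_xyz <- function(mol, path, comment = "") {
  lines <- c(
    as.character(n_atoms(mol)), comment,
    sprintf("%s %.10f %.10f %.10f", mol$elements,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  )
  writeLines(lines, path)
}
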