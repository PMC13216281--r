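# Molecular geometry handling: XYZ input, element data, nuclear repulsion.

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

#' Build a molecule object
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (natom x 3) of Cartesian coordinates.
#' @param charge total molecular charge.
#' @param unit `"angstrom"` or `"bohr"`.
#' @return object of class `molecule` with coordinates stored in bohr.
#' @export
molecule <- function(symbols, coords, charge = 0, unit = "angstrom") {
  coords <- as.matrix(coords)
  stopifnot(length(symbols) == nrow(coords), ncol(coords) == 3)
  unknown <- setdiff(symbols, names(element_numbers))
  if (length(unknown)) stop("unknown element symbol(s): ",
                            paste(unknown, collapse = ", "))
  if (unit == "angstrom") coords <- coords * BOHR_PER_ANGSTROM
  else if (unit != "bohr") stop("unit must be 'angstrom' or 'bohr'")
  Z <- unname(element_numbers[symbols])
  structure(list(symbols = symbols, coords = coords, Z = Z,
                 charge = charge, nelec = sum(Z) - charge,
                 natm = length(symbols)),
            class = "molecule")
}

#' Read a molecule from an XYZ file
#'
#' Standard format: atom count, comment line, then one
#' `symbol x y z` line per atom (coordinates in Angstrom).
#'
#' @param path file path.
#' @param charge total charge (not stored in plain XYZ).
#' @return `molecule`.
#' @export
read_xyz <- function(path, charge = 0) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  symbols <- vapply(rows, `[[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(symbols, coords, charge = charge)
}

#' Write a molecule to an XYZ file
#' @param mol `molecule`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, comment = "") {
  ang <- mol$coords / BOHR_PER_ANGSTROM
  lines <- c(as.character(mol$natm), comment,
             sprintf("%s %.8f %.8f %.8f", mol$symbols,
                     ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
}

#' Nuclear repulsion energy (hartree)
#' @param mol `molecule`.
#' @export
nuclear_repulsion <- function(mol) {
  e <- 0
  if (mol$natm < 2) return(0)
  for (i in 1:(mol$natm - 1)) for (j in (i + 1):mol$natm) {
    r <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    e <- e + mol$Z[i] * mol$Z[j] / r
  }
  e
}

#' @export
print.molecule <- function(x, ...) {
  cat("molecule:", x$natm, "atoms, charge", x$charge, ",",
      x$nelec, "electrons\n")
  invisible(x)
}
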