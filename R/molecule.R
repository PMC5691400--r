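#' Construct a molecule from atomic coordinates and radii
#'
#' A molecule is the substrate of both Gaussian fields: an ordered set of
#' atomic centres \eqn{x_i} with van der Waals radii \eqn{r_i}.
#'
#' @param x,y,z Numeric vectors of atomic coordinates (Angstrom).
#' @param radius Numeric vector of van der Waals radii (Angstrom), recycled.
#' @param element Character vector of element symbols, recycled.
#' @param serial Integer atom identifiers; defaults to `1:n`.
#' @param label Free-text molecule label (e.g. a PDB identifier).
#' @return An object of class `molecule`: a list with an `atoms` data frame
#'   (`serial`, `element`, `x`, `y`, `z`, `radius`) and a `label`.
#' @export
molecule <- function(x, y, z, radius, element = "C",
                     serial = seq_along(x), label = "molecule") {
  n <- length(x)
  if (n < 1L) stop("a molecule needs at least one atom")
  if (length(y) != n || length(z) != n) stop("coordinate vectors differ in length")
  atoms <- data.frame(
    serial = as.integer(serial),
    element = toupper(rep_len(as.character(element), n)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    radius = rep_len(as.numeric(radius), n),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atomic coordinates must be finite")
  }
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0)) {
    stop("atomic radii must be positive")
  }
  structure(list(atoms = atoms, label = as.character(label)[1L]),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("Molecule", sQuote(x$label), "with", nrow(x$atoms), "atoms\n")
  cat("  elements:", paste(names(sort(table(x$atoms$element), decreasing = TRUE)),
                           collapse = " "), "\n")
  rng <- apply(x$atoms[, c("x", "y", "z")], 2, range)
  cat(sprintf("  extent:  x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] Angstrom\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  nrow(mol$atoms)
}

atom_centers <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) and assigns van der Waals
#' radii by element symbol. The defaults reflect how cavities are sought on
#' the protein proper: crystallographic waters are dropped, non-water
#' heteroatoms are dropped, hydrogens are kept when present, and only the
#' blank or `'A'` alternate-location conformer is retained. Multi-model files
#' contribute their first model only.
#'
#' @param file Path to a PDB file, or a character vector of PDB-format lines.
#' @param include_het Keep non-water HETATM records?
#' @param include_waters Keep water residues (HOH/WAT/DOD)?
#' @param include_hydrogens Keep hydrogen/deuterium atoms?
#' @param radius_table A `radius_table` used to assign radii.
#' @param label Molecule label; defaults to the file stem.
#' @return A `molecule`.
#' @export
read_pdb <- function(file, include_het = FALSE, include_waters = FALSE,
                     include_hydrogens = TRUE,
                     radius_table = default_radius_table(), label = NULL) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    path <- file
    if (is.null(label)) label <- sub("\\.(pdb|ent)$", "", basename(file))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), path)
    if (is.null(label)) label <- "pdb-text"
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB input: ", conditionMessage(e))
  )
  at <- pdb$atom
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    stop("malformed coordinate field in record(s) with serial ",
         paste(at$eleno[bad], collapse = ", "))
  }
  ele <- at$elesy
  missing_ele <- is.na(ele) | !nzchar(trimws(ele))
  if (any(missing_ele)) {
    # fallback: first alphabetic character of the atom name field
    ele[missing_ele] <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1",
                            at$elety[missing_ele])
  }
  ele <- toupper(trimws(ele))

  is_water <- toupper(at$resid) %in% c("HOH", "WAT", "DOD")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  keep <- keep & (include_waters | !is_water)
  keep <- keep & (at$type == "ATOM" | include_het | (include_waters & is_water))
  if (!include_hydrogens) keep <- keep & !(ele %in% c("H", "D"))
  if (!any(keep)) stop("empty molecule: no atoms survive the record filters")

  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  molecule(
    x = at$x, y = at$y, z = at$z,
    radius = assign_radius(ele, radius_table),
    element = ele, serial = at$eleno, label = label
  )
}

#' Write a molecule as a pseudo-PDB file
#'
#' Emits one fixed-column ATOM record per atom (residue `MOL`, chain `A`),
#' with the element symbol in columns 77-78, so synthetic molecules can be
#' fed to any PDB-consuming tool, including this package's own reader.
#'
#' @param mol A `molecule`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  a <- mol$atoms
  ele <- substr(a$element, 1, 2)
  # single-letter elements start the atom name at column 14
  name <- ifelse(nchar(ele) == 1L, sprintf(" %-3s", ele), sprintf("%-4s", ele))
  rec <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name, "MOL", "A",
    (seq_len(nrow(a)) - 1L) %% 9999L + 1L,
    a$x, a$y, a$z, 1, 0, ele
  )
  writeLines(c(rec, "END"), path)
  invisible(path)
}
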