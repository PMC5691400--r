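#' Default van der Waals radius table
#'
#' Bondi-style van der Waals radii for the elements most common in protein
#' structures, plus the halogens. Elements absent from the table fall back to
#' the carbon radius of 1.70 Angstrom, which keeps a sensible molecular
#' envelope for exotic atoms.
#'
#' @return An object of class `radius_table`: a list with a named numeric
#'   vector `radii` (Angstrom) and a scalar `default`.
#' @examples
#' tab <- default_radius_table()
#' assign_radius("C", tab)
#' @export
default_radius_table <- function() {
  radii <- c(
    H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52,
    S = 1.80, P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
  )
  radius_table(radii, default = 1.70)
}

#' Construct a van der Waals radius table
#'
#' @param radii Named numeric vector of radii in Angstrom; names are element
#'   symbols (case-insensitive, stored upper-case).
#' @param default Radius used for elements absent from `radii`.
#' @return An object of class `radius_table`.
#' @export
radius_table <- function(radii, default = 1.70) {
  radii <- unlist(radii)
  if (is.null(names(radii)) || any(!nzchar(names(radii)))) {
    stop("all radii must be named by element symbol")
  }
  if (!all(is.finite(radii)) || !is.finite(default)) {
    stop("radii must be finite")
  }
  if (any(radii <= 0.5 | radii >= 3.0) || default <= 0.5 || default >= 3.0) {
    stop("van der Waals radii must lie in (0.5, 3.0) Angstrom")
  }
  names(radii) <- toupper(names(radii))
  structure(list(radii = radii, default = default), class = "radius_table")
}

#' Read a radius table override from a key=value text file
#'
#' Each non-comment line has the form `ELEMENT = radius`; the special key
#' `default` overrides the fallback radius. Entries merge into (and override)
#' the built-in table.
#'
#' @param path Path to the configuration file.
#' @param base Table to override; defaults to [default_radius_table()].
#' @return A `radius_table`.
#' @export
read_radius_table <- function(path, base = default_radius_table()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  radii <- base$radii
  default <- base$default
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed radius table line: ", sQuote(ln))
    key <- toupper(trimws(parts[1L]))
    val <- suppressWarnings(as.numeric(trimws(parts[2L])))
    if (!is.finite(val)) stop("malformed radius value in line: ", sQuote(ln))
    if (key == "DEFAULT") default <- val else radii[key] <- val
  }
  radius_table(radii, default = default)
}

#' Assign van der Waals radii to element symbols
#'
#' Unknown symbols receive the table default with a warning, so parsing never
#' fails on an exotic element.
#'
#' @param element Character vector of element symbols.
#' @param table A `radius_table`.
#' @return Numeric vector of radii (Angstrom), one per element.
#' @export
assign_radius <- function(element, table = default_radius_table()) {
  stopifnot(inherits(table, "radius_table"))
  element <- toupper(as.character(element))
  if (any(!nzchar(element)) || anyNA(element)) {
    stop("element symbols must be non-empty")
  }
  r <- unname(table$radii[element])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(
      "unknown element symbol(s) ",
      paste(sQuote(unique(element[unknown])), collapse = ", "),
      "; using default radius ", format(table$default), " Angstrom"
    )
    r[unknown] <- table$default
  }
  r
}
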