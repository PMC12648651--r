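# XYZ file I/O.
#
# Strict two-header-line dialect: line 1 is the atom count, line 2 a free
# comment (the writer stores "name rank=n energy=E" metadata there), then one
# "element x y z" row per atom.  Trailing columns after z are ignored on
# read.  Coordinates are written with six decimal places so repeated runs
# diff bit-stably.

#' Read an XYZ geometry file
#'
#' @param path Path to an XYZ file.
#' @param name Molecule name; defaults to the file base name.
#' @return A [molecule()] whose coordinates are the file geometry and whose
#'   `comment` holds the file's comment line.  Bonds are not perceived here;
#'   see [perceive_bonds()].
#' @export
read_xyz <- function(path, name = NULL) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("XYZ parse error at line 1: empty file")
  count <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(count) || count <= 0 ||
      trimws(lines[1]) != as.character(count)) {
    stop("XYZ parse error at line 1: count line must be a positive integer, got '",
         trimws(lines[1]), "'")
  }
  if (length(lines) < count + 2) {
    stop("XYZ parse error: count line declares ", count, " atoms but only ",
         max(0, length(lines) - 2), " atom lines present")
  }
  comment <- if (length(lines) >= 2) lines[2] else ""
  elements <- character(count)
  coords <- matrix(NA_real_, count, 3)
  for (k in seq_len(count)) {
    ln <- k + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) {
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    }
    if (!tok[1] %in% .ELEMENTS) {
      stop("XYZ parse error at line ", ln, ": '", tok[1],
           "' is not an element symbol")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    }
    elements[k] <- tok[1]
    coords[k, ] <- xyz
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  molecule(name, elements, coords, comment = comment)
}

#' Write a conformer as an XYZ file
#'
#' @param conf A [conformer()].
#' @param elements Character vector of element symbols matching the
#'   conformer's atom count (usually `mol$elements`).
#' @param path Output file path.
#' @param comment Comment line; defaults to the conformer id plus its energy
#'   when present.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(conf, elements, path, comment = NULL) {
  stopifnot(inherits(conf, "conformer"))
  n <- nrow(conf$coords)
  if (n == 0) stop("refusing to write an XYZ file with 0 atoms")
  if (length(elements) != n) {
    stop("elements length (", length(elements), ") != atom count (", n, ")")
  }
  if (is.null(comment)) {
    comment <- conf$conf_id
    if (!is.na(conf$energy)) {
      comment <- sprintf("%s energy=%.6f", comment, conf$energy)
    }
  }
  rows <- sprintf("%-2s %12.6f %12.6f %12.6f", elements,
                  conf$coords[, 1], conf$coords[, 2], conf$coords[, 3])
  ok <- tryCatch({
    writeLines(c(as.character(n), comment, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write XYZ file: ", path)
  invisible(path)
}

#' Write a molecule's reference geometry as an XYZ file
#'
#' Convenience wrapper around [write_xyz()] using the molecule's own
#' coordinates and name.
#'
#' @param mol A [molecule()].
#' @param path Output file path.
#' @param comment Optional comment line; defaults to the molecule name.
#' @return `path`, invisibly.
#' @export
write_molecule_xyz <- function(mol, path, comment = NULL) {
  if (is.null(comment)) comment <- mol$name
  write_xyz(conformer(mol$name, mol$coords), mol$elements, path,
            comment = comment)
}
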