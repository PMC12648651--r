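# Core data model: molecules, conformers, ensembles.
#
# All coordinates are in Angstrom, energies in kcal/mol, CCS in Angstrom^2.
# Atom ordering is significant everywhere: conformers of one molecule share
# the molecule's atom order, which is what makes coordinate RMSD meaningful.

# Periodic-table symbols accepted by the parsers (H-Rn covers anything an
# IM-MS small-molecule workflow will meet).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

# Bondi van der Waals radii (Angstrom); elements without a tabulated Bondi
# value fall back to 1.70.
.VDW_RADII <- c(
  H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98,
  Xe = 2.16
)

#' Van der Waals radius of an element
#'
#' Bondi radii, with a 1.70 Angstrom fallback for elements outside the
#' tabulated set.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct a molecule
#'
#' A molecule is an ordered atom list (element + reference position), a bond
#' list (index pairs with integer order), a formal charge and a name.  Within
#' this package formal charges are restricted to -1, 0 and +1: the pipeline
#' handles neutral input and singly charged adducts only.
#'
#' @param name Text label used for output folder naming.
#' @param elements Character vector of element symbols, one per atom.
#' @param coords N x 3 numeric matrix of positions (Angstrom).
#' @param bonds Data frame with integer columns `i`, `j`, `order`
#'   (1-based atom indices, i < j after normalization).
#' @param formal_charge Integer in -1..1.
#' @param comment Optional free-text metadata (e.g. the XYZ comment line).
#' @return An object of class `molecule`.
#' @export
molecule <- function(name, elements, coords, bonds = empty_bonds(),
                     formal_charge = 0L, comment = "") {
  coords <- as_coords(coords, length(elements))
  bonds <- normalize_bonds(bonds, n_atoms = length(elements))
  bad <- !(elements %in% .ELEMENTS)
  if (any(bad)) {
    stop("unknown element symbol(s): ", paste(unique(elements[bad]), collapse = ", "))
  }
  if (!formal_charge %in% c(-1L, 0L, 1L)) {
    stop("formal_charge must be -1, 0 or +1 (neutral input, singly charged adducts)")
  }
  structure(
    list(
      name = as.character(name)[1],
      elements = elements,
      coords = coords,
      bonds = bonds,
      formal_charge = as.integer(formal_charge),
      comment = as.character(comment)[1]
    ),
    class = "molecule"
  )
}

empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = integer(0))
}

as_coords <- function(coords, n_atoms) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3 || nrow(coords) != n_atoms) {
    stop("coords must be an N x 3 matrix matching the atom count (", n_atoms, ")")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  dimnames(coords) <- NULL
  coords
}

normalize_bonds <- function(bonds, n_atoms) {
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0) return(empty_bonds())
  i <- as.integer(pmin(bonds$i, bonds$j))
  j <- as.integer(pmax(bonds$i, bonds$j))
  ord <- as.integer(bonds$order)
  if (any(i < 1L | j > n_atoms)) stop("bond atom index out of range")
  if (any(i == j)) stop("self-bonds are not allowed")
  key <- paste(i, j)
  if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
  out <- data.frame(i = i, j = j, order = ord)
  out[order(out$i, out$j), , drop = FALSE]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds, charge %+d\n",
              x$name, length(x$elements), nrow(x$bonds), x$formal_charge))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

#' Construct a conformer
#'
#' One geometry of a molecule.  The coordinate matrix must match the parent
#' molecule's atom count; energy (kcal/mol) and predicted CCS (Angstrom^2)
#' are optional annotations added by downstream stages.
#'
#' @param conf_id Text identifier, unique within an ensemble.
#' @param coords N x 3 numeric matrix (Angstrom).
#' @param energy Scalar energy in kcal/mol, or `NA`.
#' @param ccs_pred Predicted CCS in Angstrom^2, or `NA`.
#' @return An object of class `conformer`.
#' @export
conformer <- function(conf_id, coords, energy = NA_real_, ccs_pred = NA_real_) {
  coords <- as_coords(coords, nrow(as.matrix(coords)))
  if (nrow(coords) == 0) stop("a conformer needs at least one atom")
  energy <- as.numeric(energy)[1]
  ccs_pred <- as.numeric(ccs_pred)[1]
  if (!is.na(energy) && !is.finite(energy)) stop("energy must be finite")
  if (!is.na(ccs_pred) && (!is.finite(ccs_pred) || ccs_pred <= 0)) {
    stop("ccs_pred must be finite and positive")
  }
  structure(
    list(conf_id = as.character(conf_id)[1], coords = coords,
         energy = energy, ccs_pred = ccs_pred),
    class = "conformer"
  )
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %s: %d atoms%s%s\n", x$conf_id, nrow(x$coords),
              if (is.na(x$energy)) "" else sprintf(", E = %.3f kcal/mol", x$energy),
              if (is.na(x$ccs_pred)) "" else sprintf(", CCS = %.2f A^2", x$ccs_pred)))
  invisible(x)
}

#' Construct a conformer ensemble
#'
#' An ordered conformer collection sharing one molecule (and therefore one
#' atom ordering), tagged with the charge-model rank it belongs to.
#'
#' @param mol A [molecule()].
#' @param conformers List of [conformer()] objects.
#' @param rank_label Integer charge-model rank (used in `opt_Rank[n]` paths).
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(mol, conformers = list(), rank_label = 1L) {
  stopifnot(inherits(mol, "molecule"))
  for (cf in conformers) {
    stopifnot(inherits(cf, "conformer"))
    if (nrow(cf$coords) != n_atoms(mol)) {
      stop("conformer ", cf$conf_id, " atom count (", nrow(cf$coords),
           ") does not match molecule (", n_atoms(mol), ")")
    }
  }
  ids <- vapply(conformers, `[[`, character(1), "conf_id")
  if (anyDuplicated(ids)) stop("conf_ids must be unique within an ensemble")
  structure(
    list(molecule = mol, conformers = conformers,
         rank_label = as.integer(rank_label)),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> rank %d: %d conformers of %s (%d atoms)\n",
              x$rank_label, length(x$conformers), x$molecule$name,
              n_atoms(x$molecule)))
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$conformers)

ensemble_energies <- function(ens) {
  vapply(ens$conformers, `[[`, numeric(1), "energy")
}

ensemble_ids <- function(ens) {
  vapply(ens$conformers, `[[`, character(1), "conf_id")
}

# Subset an ensemble by conformer positions, preserving order.
ensemble_subset <- function(ens, idx) {
  ensemble(ens$molecule, ens$conformers[idx], rank_label = ens$rank_label)
}
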