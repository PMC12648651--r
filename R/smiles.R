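# SMILES input and bond perception.
#
# SMILES parsing and 3-D embedding are delegated to RDKit (via the system
# Python): its distance-geometry embedder accepts a random seed, which is
# what makes whole-pipeline runs reproducible.  Geometry quality only needs
# to be good enough to seed torsion-grid generation.  Bond perception for
# raw XYZ input goes through Open Babel (ChemmineOB), the standard tool for
# recovering connectivity from bare coordinates.

.EMBED_PY <- paste(
  "import sys",
  "from rdkit import Chem",
  "from rdkit.Chem import AllChem",
  "smi, seed = sys.argv[1], int(sys.argv[2])",
  "m = Chem.MolFromSmiles(smi)",
  "if m is None: sys.exit(64)",
  "if Chem.GetFormalCharge(m) != 0: sys.exit(65)",
  "m = Chem.AddHs(m)",
  "p = AllChem.ETKDGv3()",
  "p.randomSeed = seed",
  "if AllChem.EmbedMolecule(m, p) != 0:",
  "    p.useRandomCoords = True",
  "    if AllChem.EmbedMolecule(m, p) != 0: sys.exit(66)",
  "sys.stdout.write(Chem.MolToMolBlock(m, kekulize=True))",
  sep = "\n"
)

#' Parse a neutral SMILES string into a 3-D molecule
#'
#' Adds explicit hydrogens and embeds one deterministic 3-D geometry
#' (seeded distance-geometry via RDKit).  Only neutral input is accepted:
#' charging happens downstream when adduct charge models are built.
#'
#' @param smiles SMILES string of a neutral molecule.
#' @param name Molecule name; defaults to the SMILES string.
#' @param seed Integer seed for the 3-D embedding (default 42).
#' @return A [molecule()] with explicit hydrogens, perceived bonds and one
#'   embedded geometry.
#' @export
parse_smiles <- function(smiles, name = smiles, seed = 42L) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles))) {
    stop("smiles must be a non-empty string")
  }
  out <- suppressWarnings(system2("python", c("-c", shQuote(.EMBED_PY),
                                              shQuote(smiles),
                                              as.integer(seed)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status)) {
    if (status == 64) stop("unparsable SMILES: '", smiles, "'")
    if (status == 65) stop("SMILES '", smiles, "' carries a net formal charge; ",
                           "this pipeline requires neutral input (charge models ",
                           "are generated internally)")
    if (status == 66) stop("3-D embedding failed for SMILES '", smiles, "'")
    stop("SMILES embedding subprocess failed (status ", status, "); ",
         "is Python with RDKit on the PATH?")
  }
  molblock_to_molecule(out, name = name)
}

# Convert V2000 molblock lines to a molecule.  When coords is given it
# overrides the molblock coordinate block (used for XYZ input, where Open
# Babel's conversion keeps atom order but rewrites coordinates).
molblock_to_molecule <- function(lines, name, coords = NULL,
                                 formal_charge = 0L, comment = "") {
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(c(lines, "$$$$")))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  if (is.null(coords)) coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- if (is.null(bb) || nrow(bb) == 0) empty_bonds() else
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  molecule(name, elements, coords, bonds = bonds,
           formal_charge = formal_charge, comment = comment)
}

#' Perceive bonds for a molecule from its geometry
#'
#' Runs Open Babel's distance-based connectivity and bond-order perception
#' on the molecule's coordinates and returns the molecule with its bond
#' table filled in.  Atom order and coordinates are untouched.
#'
#' @param mol A [molecule()], typically from [read_xyz()].
#' @return The molecule with perceived `bonds`.
#' @export
perceive_bonds <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  rows <- sprintf("%s %.6f %.6f %.6f", mol$elements,
                  mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  xyz <- paste(c(as.character(n_atoms(mol)), mol$name, rows), collapse = "\n")
  sdf <- ChemmineOB::convertFormat("XYZ", "SDF", source = xyz)
  out <- molblock_to_molecule(strsplit(sdf, "\n")[[1]], name = mol$name,
                              coords = mol$coords,
                              formal_charge = mol$formal_charge,
                              comment = mol$comment)
  if (!identical(out$elements, mol$elements)) {
    stop("bond perception changed the atom ordering; refusing to continue")
  }
  out
}
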