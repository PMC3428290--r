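# Built-in chemical vocabularies: element masses, residue-name classes,
# base/side-chain atom sets, hydrogen-bond donors and acceptors.
# Hydrogens are optional everywhere; every table below is heavy-atom based.

# Atomic masses (Da), standard atomic weights.
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762,
  S = 32.06, F = 18.998403, CL = 35.45, BR = 79.904, I = 126.90447,
  "NA" = 22.98977, MG = 24.305, K = 39.0983, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938
)

.PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT")

# Hydrophobic residues considered in the side-chain contact census.
.HYDROPHOBIC_RESNAMES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

# Positively charged residues and their charged-group atoms
# (terminal side-chain group carrying the formal charge).
.CHARGED_GROUP <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2", "CE1", "CD2", "CG")
)

# Base moiety per one-letter base identity: ring heavy atoms plus exocyclic
# N/O substituents (no sugar, no phosphate).
.BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

# Heavy-atom hydrogen-bond donors and acceptors.
.PROTEIN_DONORS <- list(
  .backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG"
)
.PROTEIN_ACCEPTORS <- list(
  .backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)
.RNA_DONORS <- list(
  A = "N6", G = c("N1", "N2"), C = "N4", U = "N3",
  .sugar = "O2'"
)
.RNA_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"), G = c("N3", "N7", "O6"),
  C = c("O2", "N3"), U = c("O2", "O4"),
  .backbone = c("OP1", "OP2", "O1P", "O2P", "O2'", "O3'", "O4'", "O5'")
)

# Coarse side-chain atom sets used by the synthetic residue builder; real
# structures simply contribute whatever non-backbone atoms they carry.
.SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  PRO = c("CB", "CG", "CD"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  MET = c("CB", "CG", "SD", "CE"),
  TRP = c("CB", "CG", "CD1", "NE1", "CE2", "CD2"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  CYS = c("CB", "SG"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  GLY = character(0)
)

#' Map an RNA residue name to its one-letter base identity
#'
#' Accepts the plain names `A`, `U`, `G`, `C` as well as the `R`-prefixed
#' (`RA`, ...) and 5'/3'-terminal (`A5`, `U3`, ...) variants common in
#' force-field topologies.
#'
#' @param resname character vector of residue names.
#' @return character vector of `"A"`, `"U"`, `"G"`, `"C"`, or `NA` where the
#'   name is not an RNA residue.
#' @export
base_identity <- function(resname) {
  x <- toupper(trimws(resname))
  x <- sub("^R", "", x)       # RA -> A
  x <- sub("[53]$", "", x)    # A5 / U3 -> A / U
  x[!x %in% c("A", "U", "G", "C")] <- NA_character_
  x
}

#' Atomic mass lookup by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da.
#' @export
element_mass <- function(element) {
  m <- .ELEMENT_MASS[toupper(trimws(element))]
  if (anyNA(m)) {
    bad <- unique(toupper(trimws(element))[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

# Infer an element symbol from a PDB atom name when the element column is
# blank. Strips digits and primes; recognises the two-letter symbols that
# occur in biomolecules before falling back to the first letter.
.element_from_name <- function(name) {
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "MN"),
    two, substr(nm, 1, 1)
  )
}
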