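# Residue topology tables for the 20 standard amino acids: heavy-atom
# side-chain parentage (a tree hanging off CA), ring bonds, and standard
# backbone geometry used by the "ideal" rebuild mode.

AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# atom -> parent, within one residue; CB always hangs off CA.
SIDECHAIN_PARENTS <- list(
  ALA = c(CB = "CA"),
  ARG = c(CB = "CA", CG = "CB", CD = "CG", NE = "CD", CZ = "NE",
          NH1 = "CZ", NH2 = "CZ"),
  ASN = c(CB = "CA", CG = "CB", OD1 = "CG", ND2 = "CG"),
  ASP = c(CB = "CA", CG = "CB", OD1 = "CG", OD2 = "CG"),
  CYS = c(CB = "CA", SG = "CB"),
  GLN = c(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", NE2 = "CD"),
  GLU = c(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", OE2 = "CD"),
  GLY = c(),
  HIS = c(CB = "CA", CG = "CB", ND1 = "CG", CD2 = "CG", CE1 = "ND1",
          NE2 = "CD2"),
  ILE = c(CB = "CA", CG1 = "CB", CG2 = "CB", CD1 = "CG1"),
  LEU = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG"),
  LYS = c(CB = "CA", CG = "CB", CD = "CG", CE = "CD", NZ = "CE"),
  MET = c(CB = "CA", CG = "CB", SD = "CG", CE = "SD"),
  PHE = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
          CE2 = "CD2", CZ = "CE1"),
  PRO = c(CB = "CA", CG = "CB", CD = "CG"),
  SER = c(CB = "CA", OG = "CB"),
  THR = c(CB = "CA", OG1 = "CB", CG2 = "CB"),
  TRP = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", NE1 = "CD1",
          CE2 = "CD2", CE3 = "CD2", CZ2 = "CE2", CZ3 = "CE3",
          CH2 = "CZ2"),
  TYR = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
          CE2 = "CD2", CZ = "CE1", OH = "CZ"),
  VAL = c(CB = "CA", CG1 = "CB", CG2 = "CB"))

# Bonds closing rings (not covered by the parentage tree).
RING_CLOSURES <- list(
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CZ", "CE2")),
  PRO = list(c("CD", "N")),
  TRP = list(c("NE1", "CE2"), c("CH2", "CZ3")),
  TYR = list(c("CZ", "CE2")))

# All bonds that are part of a ring (both tree bonds and closures).
RING_BONDS <- list(
  HIS = list(c("CG", "ND1"), c("ND1", "CE1"), c("CE1", "NE2"),
             c("NE2", "CD2"), c("CD2", "CG")),
  PHE = list(c("CG", "CD1"), c("CD1", "CE1"), c("CE1", "CZ"),
             c("CZ", "CE2"), c("CE2", "CD2"), c("CD2", "CG")),
  PRO = list(c("N", "CA"), c("CA", "CB"), c("CB", "CG"),
             c("CG", "CD"), c("CD", "N")),
  TRP = list(c("CG", "CD1"), c("CD1", "NE1"), c("NE1", "CE2"),
             c("CE2", "CD2"), c("CD2", "CG"), c("CD2", "CE3"),
             c("CE3", "CZ3"), c("CZ3", "CH2"), c("CH2", "CZ2"),
             c("CZ2", "CE2")),
  TYR = list(c("CG", "CD1"), c("CD1", "CE1"), c("CE1", "CZ"),
             c("CZ", "CE2"), c("CE2", "CD2"), c("CD2", "CG")))

# Standard backbone/CB geometry (Engh-Huber-style values) used when the
# rebuild substitutes ideal bond lengths and angles while keeping the
# measured dihedrals.
IDEAL_GEOMETRY <- list(
  # key: atom being placed; length to parent, angle at parent.
  N  = list(length = 1.329, angle = 116.6),   # C(i-1)-N,  CA-C-N
  CA = list(length = 1.458, angle = 121.9),   # N-CA,      C-N-CA
  C  = list(length = 1.525, angle = 111.2),   # CA-C,      N-CA-C
  O  = list(length = 1.231, angle = 120.8),   # C-O,       CA-C-O
  CB = list(length = 1.530, angle = 110.5))   # CA-CB,     N-CA-CB

residueHeavyAtomNames <- function(resname) {
  sc <- SIDECHAIN_PARENTS[[resname]]
  if (is.null(sc)) stop(sprintf("unknown residue '%s'", resname))
  c("N", "CA", "C", "O", names(sc))
}

# Heavy-atom covalent bond list for a peptide given its residue names.
# Returns a data.frame with atom identifiers "<residue rank>:<name>",
# a ring flag, and an amide flag for the backbone C-N linkage.
peptideBondGraph <- function(resnames) {
  stopifnot(all(resnames %in% STANDARD_AA))
  bonds <- list()
  addBond <- function(i, a, j, b, ring = FALSE, amide = FALSE)
    bonds[[length(bonds) + 1]] <<- data.frame(
      a = paste0(i, ":", a), b = paste0(j, ":", b),
      ring = ring, amide = amide, stringsAsFactors = FALSE)
  for (i in seq_along(resnames)) {
    rn <- resnames[i]
    ringSet <- RING_BONDS[[rn]]
    isRing <- function(a, b) {
      if (is.null(ringSet)) return(FALSE)
      any(vapply(ringSet, function(p)
        setequal(p, c(a, b)), logical(1)))
    }
    addBond(i, "N", i, "CA", ring = isRing("N", "CA"))
    addBond(i, "CA", i, "C")
    addBond(i, "C", i, "O")
    for (at in names(SIDECHAIN_PARENTS[[rn]])) {
      pa <- SIDECHAIN_PARENTS[[rn]][[at]]
      addBond(i, pa, i, at, ring = isRing(pa, at))
    }
    for (cl in RING_CLOSURES[[rn]]) {
      if (cl[2] == "N" || cl[1] == "N") next  # PRO CD-N handled below
      addBond(i, cl[1], i, cl[2], ring = TRUE)
    }
    if (rn == "PRO") addBond(i, "CD", i, "N", ring = TRUE)
    if (i < length(resnames))
      addBond(i, "C", i + 1, "N", amide = TRUE)
  }
  do.call(rbind, bonds)
}
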