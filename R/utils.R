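# Internal helpers shared across modules.

# Residue key: author residue number + insertion code + residue name.
# Uniquely identifies a residue within one chain and is the unit by which
# native and model residues are paired (mismatch is an error, never a
# silent intersection).
residueKeys <- function(atoms) {
  if (!nrow(atoms)) return(character())
  paste0(atoms$resno, ifelse(nzchar(atoms$insert), atoms$insert, ""),
         ":", atoms$resname)
}

# Unique residue keys in order of first appearance.
residueOrder <- function(atoms) unique(residueKeys(atoms))

isHeavy <- function(atoms) !(toupper(atoms$element) %in% c("H", "D"))

coordMatrix <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

setCoords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# PDB rules: columns 13-14 of the atom name carry the element for standard
# residues; fall back to the first alphabetic character that is not a
# leading digit (handles names like "1HB", "CA", "OXT").
elementFromName <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    if (!nzchar(nm)) return("X")
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

# Run code with a private RNG stream: seeds deterministically, restores
# the caller's .Random.seed afterwards.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unitVec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Signed four-point torsion angle
#'
#' Standard IUPAC signed dihedral defined by four points, in degrees in
#' (-180, 180]. Looking along the p2-p3 axis, a clockwise rotation of the
#' far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 length-3 numeric coordinate vectors (A).
#' @return angle in degrees.
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossProd3(b1, b2)
  n2 <- crossProd3(b2, b3)
  m <- crossProd3(n1, b2 / vnorm(b2))
  ang <- -atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

bondAngle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
}

# Smallest absolute circular difference between two angle vectors, degrees.
angleDiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
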