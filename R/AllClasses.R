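#' @import methods
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

ATOM_COLS <- c("eleno", "elety", "resname", "chain", "resno", "insert",
               "x", "y", "z", "element")

#' PeptideComplex: a cleaned receptor/peptide two-chain complex
#'
#' Container for one protein-peptide complex after cleaning: exactly one
#' receptor chain and one peptide chain, hetero-atoms and waters removed,
#' alternate locations reduced to the 'A' set. Atoms are stored as
#' data frames with columns \code{eleno, elety, resname, chain, resno,
#' insert, x, y, z, element}; hydrogens are retained but excluded from all
#' metric computations.
#'
#' @slot pdbId identifier of the complex (character).
#' @slot receptor data.frame of receptor-chain atoms.
#' @slot peptide data.frame of peptide-chain atoms.
#' @slot receptorChain,peptideChain single-letter chain identifiers.
#' @slot resolution crystallographic resolution in Angstrom
#'   (\code{NA_real_} when unknown).
#'
#' @aliases PeptideComplex-class
#' @exportClass PeptideComplex
setClass("PeptideComplex",
  representation(pdbId = "character",
                 receptor = "data.frame",
                 peptide = "data.frame",
                 receptorChain = "character",
                 peptideChain = "character",
                 resolution = "numeric"))

validAtomTable <- function(df, what) {
  missing <- setdiff(ATOM_COLS, colnames(df))
  if (length(missing))
    return(sprintf("%s atom table lacks columns: %s", what,
                   paste(missing, collapse = ", ")))
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) && !all(is.finite(xyz)))
    return(sprintf("%s atom table has non-finite coordinates", what))
  if (nrow(df) && any(!nzchar(df$element)))
    return(sprintf("%s atom table has empty element symbols", what))
  TRUE
}

setValidity("PeptideComplex", function(object) {
  msgs <- character()
  for (side in c("receptor", "peptide")) {
    v <- validAtomTable(slot(object, side), side)
    if (!isTRUE(v)) msgs <- c(msgs, v)
  }
  if (!length(msgs)) {
    bad <- setdiff(unique(c(object@receptor$resname, object@peptide$resname)),
                   STANDARD_AA)
    if (length(bad))
      msgs <- c(msgs, sprintf("non-standard residues present: %s",
                              paste(bad, collapse = ", ")))
    npep <- length(unique(residueKeys(object@peptide)))
    if (npep < 1 || npep > 50)
      msgs <- c(msgs, sprintf("peptide length %d outside [1, 50]", npep))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PeptideComplex construct a complex from two atom tables
#' @param pdbId,receptor,peptide,receptorChain,peptideChain,resolution see slots
#' @export
PeptideComplex <- function(pdbId, receptor, peptide,
                           receptorChain = "A", peptideChain = "B",
                           resolution = NA_real_) {
  new("PeptideComplex", pdbId = pdbId,
      receptor = receptor, peptide = peptide,
      receptorChain = receptorChain, peptideChain = peptideChain,
      resolution = as.numeric(resolution))
}

#' @rdname PeptideComplex
#' @param object,x a \code{PeptideComplex}
#' @export
setGeneric("pdbId", function(x) standardGeneric("pdbId"))
#' @rdname PeptideComplex
#' @export
setMethod("pdbId", "PeptideComplex", function(x) x@pdbId)

#' @rdname PeptideComplex
#' @export
setGeneric("receptorAtoms", function(x) standardGeneric("receptorAtoms"))
#' @rdname PeptideComplex
#' @export
setMethod("receptorAtoms", "PeptideComplex", function(x) x@receptor)

#' @rdname PeptideComplex
#' @export
setGeneric("peptideAtoms", function(x) standardGeneric("peptideAtoms"))
#' @rdname PeptideComplex
#' @export
setMethod("peptideAtoms", "PeptideComplex", function(x) x@peptide)

#' @rdname PeptideComplex
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname PeptideComplex
#' @export
setMethod("resolution", "PeptideComplex", function(x) x@resolution)

setMethod("show", "PeptideComplex", function(object) {
  cat(sprintf("PeptideComplex '%s'\n", object@pdbId))
  cat(sprintf("  receptor chain %s: %d residues, %d atoms\n",
              object@receptorChain,
              length(unique(residueKeys(object@receptor))),
              nrow(object@receptor)))
  cat(sprintf("  peptide  chain %s: %d residues, %d atoms\n",
              object@peptideChain,
              length(unique(residueKeys(object@peptide))),
              nrow(object@peptide)))
  if (!is.na(object@resolution))
    cat(sprintf("  resolution: %.2f A\n", object@resolution))
  invisible(NULL)
})

#' ContactSet: native residue-residue contacts across the interface
#'
#' A pair of residues on different sides of the interface is in contact
#' when any of their heavy atoms are within the cutoff (default 5 A,
#' inclusive). The set of native contacts is the denominator of the
#' fraction of native contacts (FNAT) and the source of interface
#' residues.
#'
#' @slot pairs data.frame with columns \code{receptor}, \code{peptide}
#'   (residue keys) and \code{minDist} (A).
#' @slot cutoff contact cutoff in Angstrom.
#'
#' @aliases ContactSet-class
#' @exportClass ContactSet
setClass("ContactSet",
  representation(pairs = "data.frame", cutoff = "numeric"))

setValidity("ContactSet", function(object) {
  if (object@cutoff <= 0) return("cutoff must be > 0")
  need <- c("receptor", "peptide")
  if (!all(need %in% colnames(object@pairs)))
    return("pairs must have 'receptor' and 'peptide' columns")
  if (anyDuplicated(object@pairs[, need]))
    return("duplicated contact pairs")
  TRUE
})

#' @rdname ContactSet
#' @param x a \code{ContactSet}
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))
#' @rdname ContactSet
#' @export
setMethod("contactPairs", "ContactSet", function(x) x@pairs)

setMethod("show", "ContactSet", function(object) {
  cat(sprintf("ContactSet: %d residue pairs at %.2f A cutoff\n",
              nrow(object@pairs), object@cutoff))
  invisible(NULL)
})

setMethod("length", "ContactSet", function(x) nrow(x@pairs))

#' PoseEvaluation: the CAPRI metric triple for one docked pose
#'
#' @slot fnat fraction of native contacts recovered, in [0, 1].
#' @slot lRmsd ligand RMSD in Angstrom: peptide backbone RMSD after
#'   superposing the receptors.
#' @slot iRmsd interface RMSD in Angstrom: backbone RMSD over native
#'   interface residues after fitting on those atoms.
#' @slot rank positive integer rank of the pose.
#' @slot method label of the docking method that produced the pose.
#'
#' @aliases PoseEvaluation-class
#' @exportClass PoseEvaluation
setClass("PoseEvaluation",
  representation(fnat = "numeric", lRmsd = "numeric", iRmsd = "numeric",
                 rank = "integer", method = "character"))

setValidity("PoseEvaluation", function(object) {
  if (!is.finite(object@fnat) || object@fnat < 0 || object@fnat > 1)
    return("fnat must be a finite fraction in [0, 1]")
  if (!is.finite(object@lRmsd) || object@lRmsd < 0)
    return("lRmsd must be finite and >= 0")
  if (!is.finite(object@iRmsd) || object@iRmsd < 0)
    return("iRmsd must be finite and >= 0")
  if (object@rank < 1L) return("rank must be >= 1")
  TRUE
})

#' @rdname PoseEvaluation
#' @param fnat,lRmsd,iRmsd,rank,method see slots
#' @export
PoseEvaluation <- function(fnat, lRmsd, iRmsd, rank = 1L, method = "unknown") {
  new("PoseEvaluation", fnat = fnat, lRmsd = lRmsd, iRmsd = iRmsd,
      rank = as.integer(rank), method = method)
}

setMethod("show", "PoseEvaluation", function(object) {
  cat(sprintf("PoseEvaluation [%s, rank %d]\n", object@method, object@rank))
  cat(sprintf("  FNAT  : %6.2f %%\n", 100 * object@fnat))
  cat(sprintf("  L-RMSD: %6.2f A\n", object@lRmsd))
  cat(sprintf("  I-RMSD: %6.2f A\n", object@iRmsd))
  invisible(NULL)
})

#' @rdname PoseEvaluation
#' @param x a \code{PoseEvaluation}
#' @export
setGeneric("fnat", function(x) standardGeneric("fnat"))
#' @rdname PoseEvaluation
#' @export
setMethod("fnat", "PoseEvaluation", function(x) x@fnat)
#' @rdname PoseEvaluation
#' @export
setGeneric("lRmsd", function(x) standardGeneric("lRmsd"))
#' @rdname PoseEvaluation
#' @export
setMethod("lRmsd", "PoseEvaluation", function(x) x@lRmsd)
#' @rdname PoseEvaluation
#' @export
setGeneric("iRmsd", function(x) standardGeneric("iRmsd"))
#' @rdname PoseEvaluation
#' @export
setMethod("iRmsd", "PoseEvaluation", function(x) x@iRmsd)

#' RigidTransform: a proper rotation plus translation
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (A).
#'
#' @aliases RigidTransform-class
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthonormal")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation determinant is not +1")
  if (length(object@translation) != 3)
    return("translation must have length 3")
  TRUE
})

#' @rdname RigidTransform
#' @param rotation,translation see slots
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: %.2f deg rotation, |t| = %.2f A\n",
              ang, sqrt(sum(object@translation^2))))
  invisible(NULL)
})

#' InternalCoordinates: per-atom z-matrix rows for a peptide
#'
#' Each heavy atom beyond the first three is described by its bond length
#' to a parent atom, bond angle to a grandparent and signed dihedral to a
#' great-grandparent, over a parentage tree rooted at the first backbone
#' nitrogen. Dihedrals are what the coordinate-shifting procedure must
#' preserve.
#'
#' @slot table data.frame, one row per heavy atom: \code{idx, elety,
#'   resname, resno, insert, element, parent, gparent, ggparent, length,
#'   angle, dihedral} (lengths A, angles/dihedrals degrees).
#'
#' @aliases InternalCoordinates-class
#' @exportClass InternalCoordinates
setClass("InternalCoordinates", representation(table = "data.frame"))

setValidity("InternalCoordinates", function(object) {
  tb <- object@table
  need <- c("idx", "elety", "resname", "resno", "insert", "element",
            "parent", "gparent", "ggparent", "length", "angle", "dihedral")
  if (!all(need %in% colnames(tb)))
    return("missing z-matrix columns")
  if (nrow(tb) < 3) return("need at least 3 atoms")
  full <- tb[-(1:3), , drop = FALSE]
  if (nrow(full)) {
    if (any(full$length <= 0.8 | full$length >= 2.0))
      return("bond length outside (0.8, 2.0) A")
    if (any(full$angle <= 0 | full$angle >= 180))
      return("bond angle outside (0, 180) degrees")
    if (any(full$dihedral <= -180 | full$dihedral > 180))
      return("dihedral outside (-180, 180]")
    if (any(full$parent >= full$idx))
      return("parent must precede atom (tree order)")
  }
  TRUE
})

setMethod("show", "InternalCoordinates", function(object) {
  cat(sprintf("InternalCoordinates: %d heavy atoms, %d residues\n",
              nrow(object@table),
              length(unique(paste(object@table$resno, object@table$insert)))))
  invisible(NULL)
})

#' @rdname InternalCoordinates
#' @param x an \code{InternalCoordinates}
#' @export
setGeneric("icTable", function(x) standardGeneric("icTable"))
#' @rdname InternalCoordinates
#' @export
setMethod("icTable", "InternalCoordinates", function(x) x@table)

#' ShiftReport: outcome of de-biasing a peptide's coordinates
#'
#' @slot bRmsd backbone RMSD (A) between original and rebuilt peptide
#'   after optimal superposition (conformation-only comparison).
#' @slot displacement distance (A) between the heavy-atom centroids of
#'   the original and shifted peptide.
#' @slot seed integer seed used for the random placement.
#' @slot mode geometry mode used for the rebuild ("measured" or "ideal").
#' @slot attempts number of placement attempts used.
#'
#' @aliases ShiftReport-class
#' @exportClass ShiftReport
setClass("ShiftReport",
  representation(bRmsd = "numeric", displacement = "numeric",
                 seed = "integer", mode = "character",
                 attempts = "integer"))

setMethod("show", "ShiftReport", function(object) {
  cat("ShiftReport\n")
  cat(sprintf("  B-RMSD      : %.4f A (%s geometry)\n",
              object@bRmsd, object@mode))
  cat(sprintf("  displacement: %.2f A\n", object@displacement))
  cat(sprintf("  seed %d, %d placement attempt(s)\n",
              object@seed, object@attempts))
  invisible(NULL)
})
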