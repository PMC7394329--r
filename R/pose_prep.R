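# pose_prep: de-biasing peptide starting coordinates for blind docking.
#
# The peptide's Cartesian coordinates are converted to internal
# coordinates (a z-matrix over a parentage tree rooted at the first
# backbone nitrogen), rebuilt in a canonical frame, and rigidly moved far
# from the receptor. Dihedral angles are preserved exactly by
# construction; bond lengths and angles are either reused ("measured",
# lossless up to rigid motion) or replaced by standard backbone values
# ("ideal", which perturbs the backbone RMSD slightly, as an external
# rebuilding toolchain would).

# Build order and global parentage for a peptide's heavy atoms.
# Returns a data.frame: elety, resname, resno, insert, element, row
# (index into the input atom table), parent/gparent/ggparent (build
# indices, NA where not applicable).
peptideTree <- function(atoms) {
  atoms <- atoms[isHeavy(atoms), , drop = FALSE]
  keys <- residueKeys(atoms)
  resKeys <- unique(keys)
  if (!length(resKeys)) stop("empty peptide")
  rows <- list(); parentName <- character()
  for (i in seq_along(resKeys)) {
    res <- atoms[keys == resKeys[i], , drop = FALSE]
    rn <- res$resname[1]
    need <- c("N", "CA", "C", "O")
    if (!all(need %in% res$elety))
      stop(sprintf("residue %s lacks a complete backbone (%s)",
                   resKeys[i],
                   paste(setdiff(need, res$elety), collapse = ", ")))
    sc <- SIDECHAIN_PARENTS[[rn]]
    order <- c(need, intersect(names(sc), res$elety))
    extra <- setdiff(res$elety, c(order, "OXT"))
    if (length(extra))
      warning(sprintf("residue %s: unrecognised heavy atoms skipped: %s",
                      resKeys[i], paste(extra, collapse = ", ")),
              call. = FALSE)
    if ("OXT" %in% res$elety) order <- c(order, "OXT")
    for (at in order) {
      r <- res[res$elety == at, , drop = FALSE][1, ]
      pn <- switch(at,
                   N = if (i == 1) NA_character_ else paste0(i - 1, ":C"),
                   CA = paste0(i, ":N"),
                   C = paste0(i, ":CA"),
                   O = paste0(i, ":C"),
                   OXT = paste0(i, ":C"),
                   paste0(i, ":", sc[[at]]))
      rows[[length(rows) + 1]] <- data.frame(
        elety = at, resname = rn, resno = r$resno, insert = r$insert,
        element = r$element, row = as.integer(rownames(res)[res$elety == at][1]),
        atomId = paste0(i, ":", at), parentName = pn,
        stringsAsFactors = FALSE)
    }
  }
  tb <- do.call(rbind, rows)
  idx <- seq_len(nrow(tb))
  lookup <- stats::setNames(idx, tb$atomId)
  tb$parent <- ifelse(is.na(tb$parentName), NA_integer_,
                      lookup[tb$parentName])
  tb$gparent <- tb$parent
  tb$gparent[!is.na(tb$parent)] <- tb$parent[tb$parent[!is.na(tb$parent)]]
  tb$ggparent <- tb$gparent
  tb$ggparent[!is.na(tb$gparent)] <- tb$parent[tb$gparent[!is.na(tb$gparent)]]
  # great-grandparent fallback: when the chain up the tree ends early
  # (CB of the first residue reaches the root N), use that residue's C,
  # which is already placed.
  for (k in which(idx > 3 & is.na(tb$ggparent))) {
    cand <- lookup[paste0(sub(":.*", "", tb$atomId[k]), ":C")]
    if (cand %in% c(tb$parent[k], tb$gparent[k]))
      stop("cannot find a distinct dihedral reference atom")
    tb$ggparent[k] <- cand
  }
  tb$idx <- idx
  tb
}

#' Convert a peptide to internal coordinates
#'
#' Computes, for every heavy atom beyond the first three in the build
#' order, its bond length to a parent atom, bond angle to a grandparent
#' and signed four-point dihedral to a great-grandparent. The backbone
#' dihedrals are exactly phi, psi and omega. A gap of more than 2.5 A
#' between consecutive backbone C and N atoms is a chain break and an
#' error.
#'
#' @param atoms peptide atom data.frame with a complete backbone
#'   (N, CA, C, O) per residue; missing side-chain atoms are tolerated.
#' @return an \linkS4class{InternalCoordinates}.
#' @export
toInternal <- function(atoms) {
  atoms <- atoms[isHeavy(atoms), , drop = FALSE]
  rownames(atoms) <- NULL
  tb <- peptideTree(atoms)
  xyz <- coordMatrix(atoms)[tb$row, , drop = FALSE]
  # chain-break check on consecutive C -> N distances
  nIdx <- which(tb$elety == "N")
  cIdx <- which(tb$elety == "C")
  if (length(nIdx) > 1) {
    gaps <- sqrt(rowSums((xyz[cIdx[-length(cIdx)], , drop = FALSE] -
                          xyz[nIdx[-1], , drop = FALSE])^2))
    if (any(gaps > 2.5))
      stop(sprintf("chain break: C-N gap of %.2f A between residues %d and %d",
                   max(gaps), which.max(gaps), which.max(gaps) + 1))
  }
  n <- nrow(tb)
  len <- ang <- dih <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    p <- tb$parent[k]; g <- tb$gparent[k]; gg <- tb$ggparent[k]
    if (!is.na(p)) len[k] <- vnorm(xyz[k, ] - xyz[p, ])
    if (!is.na(g) && k >= 3) ang[k] <- bondAngle(xyz[g, ], xyz[p, ], xyz[k, ])
    if (!is.na(gg) && k >= 4)
      dih[k] <- torsionAngle(xyz[gg, ], xyz[g, ], xyz[p, ], xyz[k, ])
  }
  tab <- data.frame(idx = tb$idx, elety = tb$elety, resname = tb$resname,
                    resno = tb$resno, insert = tb$insert,
                    element = tb$element,
                    parent = tb$parent, gparent = tb$gparent,
                    ggparent = tb$ggparent,
                    length = len, angle = ang, dihedral = dih,
                    stringsAsFactors = FALSE)
  new("InternalCoordinates", table = tab)
}

idealValue <- function(elety, measuredLength, measuredAngle) {
  g <- IDEAL_GEOMETRY[[elety]]
  if (is.null(g)) c(measuredLength, measuredAngle)
  else c(g$length, g$angle)
}

#' Rebuild a peptide from internal coordinates
#'
#' Sequential natural-extension placement: the first atom sits at the
#' origin, the second on the +x axis, the third in the xy-plane; every
#' further atom is placed from its (length, angle, dihedral) row. With
#' \code{geometry = "measured"} the stored bond lengths and angles are
#' reused and the round trip is exact up to rigid motion. With
#' \code{geometry = "ideal"} standard backbone and CB bond lengths and
#' angles replace the measured ones while every dihedral is kept, which
#' emulates rebuilding with a template-based toolchain and perturbs the
#' backbone RMSD slightly. Side-chain atoms beyond CB always keep their
#' measured geometry.
#'
#' @param ic an \linkS4class{InternalCoordinates}.
#' @param geometry \code{"measured"} or \code{"ideal"}.
#' @return peptide atom data.frame in build order, in the canonical
#'   origin frame.
#' @export
rebuildPeptide <- function(ic, geometry = c("measured", "ideal")) {
  geometry <- match.arg(geometry)
  tb <- icTable(ic)
  n <- nrow(tb)
  xyz <- matrix(NA_real_, n, 3)
  getLA <- function(k) {
    if (geometry == "ideal") idealValue(tb$elety[k], tb$length[k], tb$angle[k])
    else c(tb$length[k], tb$angle[k])
  }
  la2 <- getLA(2)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(la2[1], 0, 0)
  la3 <- getLA(3)
  th <- la3[2] * pi / 180
  xyz[3, ] <- xyz[2, ] + la3[1] * c(-cos(th), sin(th), 0)
  for (k in seq_len(n)[-(1:3)]) {
    la <- getLA(k)
    xyz[k, ] <- placeAtom(xyz[tb$ggparent[k], ], xyz[tb$gparent[k], ],
                          xyz[tb$parent[k], ], la[1], la[2], tb$dihedral[k])
  }
  data.frame(eleno = seq_len(n), elety = tb$elety, resname = tb$resname,
             chain = "", resno = as.integer(tb$resno), insert = tb$insert,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = tb$element, stringsAsFactors = FALSE)
}

# NeRF placement: X such that |X-C| = r, angle(X,C,B) = theta and
# torsion(A,B,C,X) = phi (degrees).
placeAtom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- unitVec(C - B)
  n <- unitVec(crossProd3(B - A, bc))
  m <- crossProd3(n, bc)
  C + (-r * cos(th)) * bc + (r * sin(th) * cos(ph)) * m +
    (r * sin(th) * sin(ph)) * n
}

#' All internal dihedrals of a peptide
#'
#' Convenience accessor: the named dihedral column of
#' \code{\link{toInternal}}, used to check dihedral preservation.
#'
#' @param atoms peptide atom data.frame.
#' @return named numeric vector of dihedrals in degrees; names are
#'   "residueRank:atomName".
#' @export
peptideDihedrals <- function(atoms) {
  tb <- icTable(toInternal(atoms))
  d <- tb$dihedral
  names(d) <- paste0(match(paste(tb$resno, tb$insert),
                           unique(paste(tb$resno, tb$insert))),
                     ":", tb$elety)
  d[!is.na(d)]
}

#' Backbone phi/psi/omega dihedrals of a peptide
#'
#' @param atoms peptide atom data.frame.
#' @return data.frame with columns \code{residue}, \code{phi},
#'   \code{psi}, \code{omega} (degrees; NA where undefined at the
#'   termini).
#' @export
backboneDihedrals <- function(atoms) {
  tb <- icTable(toInternal(atoms))
  nres <- length(unique(paste(tb$resno, tb$insert)))
  rank <- match(paste(tb$resno, tb$insert), unique(paste(tb$resno, tb$insert)))
  phi <- psi <- omega <- rep(NA_real_, nres)
  # psi_i    = dihedral row of N(i+1);  omega_i = dihedral row of CA(i+1)
  # phi_i    = dihedral row of C(i), defined for i >= 2
  for (i in seq_len(nres)) {
    if (i >= 2) phi[i] <- tb$dihedral[tb$elety == "C" & rank == i]
    if (i < nres) {
      psi[i] <- tb$dihedral[tb$elety == "N" & rank == i + 1]
      omega[i] <- tb$dihedral[tb$elety == "CA" & rank == i + 1]
    }
  }
  data.frame(residue = seq_len(nres), phi = phi, psi = psi, omega = omega)
}

#' Centroid displacement between two peptides
#'
#' Euclidean distance between the heavy-atom centroids.
#'
#' @param a,b peptide atom data.frames.
#' @return distance in Angstrom.
#' @export
displacement <- function(a, b) {
  ca <- colMeans(coordMatrix(a[isHeavy(a), , drop = FALSE]))
  cb <- colMeans(coordMatrix(b[isHeavy(b), , drop = FALSE]))
  vnorm(ca - cb)
}

#' Shift a peptide's Cartesian coordinates without changing its structure
#'
#' Rebuilds the peptide from its internal coordinates in the canonical
#' origin frame (so the original placement information is lost), then
#' rigidly moves it with a seeded random rotation and translation so that
#' its centroid lies at least \code{minCentroidDist} from the receptor
#' centroid and no shifted heavy atom comes within \code{minAtomDist} of
#' any receptor heavy atom. Dihedral angles of the original and shifted
#' peptide are identical; the conformation change is quantified by the
#' backbone RMSD (B-RMSD) in the returned report.
#'
#' @param x a \linkS4class{PeptideComplex}.
#' @param geometry rebuild mode, \code{"measured"} (lossless) or
#'   \code{"ideal"}.
#' @param seed integer seed for the random placement.
#' @param minCentroidDist minimum shifted-peptide-to-receptor centroid
#'   distance (A).
#' @param minAtomDist minimum heavy-atom separation from the receptor
#'   (A).
#' @param maxAttempts placement attempts before giving up.
#' @return list with \code{peptide} (shifted atom data.frame) and
#'   \code{report} (a \linkS4class{ShiftReport}).
#' @export
shiftPeptide <- function(x, geometry = c("measured", "ideal"), seed = 1L,
                         minCentroidDist = 50, minAtomDist = 20,
                         maxAttempts = 1000L) {
  geometry <- match.arg(geometry)
  pep <- peptideAtoms(x)
  ic <- toInternal(pep)
  rebuilt <- rebuildPeptide(ic, geometry)
  bR <- computeBrmsd(pep, rebuilt)
  recXyz <- heavyAtoms(receptorAtoms(x))$xyz
  recCentroid <- colMeans(recXyz)
  recRadius <- sqrt(max(rowSums(sweep(recXyz, 2, recCentroid)^2)))
  pepXyz <- coordMatrix(rebuilt)
  pepCentroid <- colMeans(pepXyz)
  pepRadius <- sqrt(max(rowSums(sweep(pepXyz, 2, pepCentroid)^2)))
  origCentroid <- colMeans(coordMatrix(pep[isHeavy(pep), , drop = FALSE]))
  shifted <- NULL; used <- 0L
  withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      R <- randomRotation()
      u <- unitVec(stats::rnorm(3))
      D <- max(minCentroidDist,
               recRadius + pepRadius + minAtomDist + 5) +
        5 * ((attempt - 1) %/% 50)
      target <- recCentroid + D * u
      cand <- sweep(pepXyz, 2, pepCentroid) %*% t(R)
      cand <- sweep(cand, 2, target, "+")
      mind2 <- min(outer(rowSums(cand^2), rowSums(recXyz^2), "+") -
                     2 * cand %*% t(recXyz))
      if (sqrt(max(mind2, 0)) >= minAtomDist &&
          vnorm(target - recCentroid) >= minCentroidDist &&
          vnorm(target - origCentroid) >= minCentroidDist) {
        shifted <- setCoords(rebuilt, cand)
        used <- attempt
        break
      }
    }
  })
  if (is.null(shifted))
    stop(sprintf("could not place the shifted peptide in %d attempts",
                 maxAttempts))
  report <- new("ShiftReport", bRmsd = bR,
                displacement = displacement(pep, shifted),
                seed = as.integer(seed), mode = geometry,
                attempts = used)
  list(peptide = shifted, report = report)
}
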