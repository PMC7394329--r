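# fixtures: synthetic structure and decoy generation with known ground
# truth. Every fixture is fully determined by (parameters, seed).
#
# Peptides are built from canonical internal coordinates with side chains
# through CB (poly-alanine-like): the backbone carries every metric, and
# CB-level side chains still exercise heavy-atom contacts.

wrapAngle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

CONFORMATION_PHIPSI <- list(helix = c(-57, -47), strand = c(-119, 113))

samplePhiPsi <- function(n) {
  # two broad basins: alpha (phi ~ -63, psi ~ -43) and beta
  # (phi ~ -120, psi ~ 130)
  basin <- stats::runif(n) < 0.5
  phi <- ifelse(basin, stats::rnorm(n, -63, 10), stats::rnorm(n, -120, 15))
  psi <- ifelse(basin, stats::rnorm(n, -43, 10), stats::rnorm(n, 130, 15))
  cbind(wrapAngle(phi), wrapAngle(psi))
}

#' Build a synthetic peptide with a prescribed conformation
#'
#' Constructs a heavy-atom peptide (backbone plus CB, except glycine)
#' from canonical internal coordinates. Helix uses phi/psi =
#' (-57, -47) degrees, strand (-119, 113); coil samples phi/psi per
#' residue from a seeded distribution over the two allowed
#' (alpha and beta) basins. All peptide bonds are trans (omega = 180).
#'
#' @param sequence one-letter amino-acid string, length >= 3.
#' @param conformation \code{"helix"}, \code{"strand"} or \code{"coil"}.
#' @param seed integer seed (used by \code{"coil"} sampling and the
#'   geometry jitter).
#' @param chain chain identifier stored on the atoms.
#' @param lengthSd,angleSd standard deviations of seeded Gaussian jitter
#'   on bond lengths (A) and bond angles (degrees). Zero by default;
#'   small values (e.g. 0.015 A / 1.5 deg) emulate the deviation of
#'   crystal structures from ideal covalent geometry. Dihedrals are
#'   never jittered.
#' @return peptide atom data.frame.
#' @examples
#' pep <- makePeptide("ADKLFGAYSE", "helix")
#' backboneDihedrals(pep)
#' @export
makePeptide <- function(sequence, conformation = c("helix", "strand", "coil"),
                        seed = 1L, chain = "B", lengthSd = 0, angleSd = 0) {
  conformation <- match.arg(conformation)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) < 3) stop("sequence must have at least 3 residues")
  bad <- setdiff(letters1, names(AA_1TO3))
  if (length(bad))
    stop(sprintf("invalid residue letter(s): %s", paste(bad, collapse = ", ")))
  resnames <- unname(AA_1TO3[letters1])
  n <- length(resnames)
  pp <- if (conformation == "coil") withSeed(seed, samplePhiPsi(n))
        else matrix(CONFORMATION_PHIPSI[[conformation]], n, 2, byrow = TRUE)
  rows <- list(); idxOf <- list()
  addRow <- function(elety, resI, parent, gparent, ggparent,
                     len, ang, dih) {
    rows[[length(rows) + 1]] <<- data.frame(
      idx = length(rows) + 1L, elety = elety, resname = resnames[resI],
      resno = resI, insert = "", element = substr(elety, 1, 1),
      parent = parent, gparent = gparent, ggparent = ggparent,
      length = len, angle = ang, dihedral = dih,
      stringsAsFactors = FALSE)
    idxOf[[paste0(resI, ":", elety)]] <<- length(rows)
    invisible(NULL)
  }
  at <- function(resI, elety) {
    v <- idxOf[[paste0(resI, ":", elety)]]
    if (is.null(v)) NA_integer_ else v
  }
  G <- IDEAL_GEOMETRY
  for (i in seq_len(n)) {
    phi <- pp[i, 1]; psi <- pp[i, 2]
    if (i == 1) {
      addRow("N", 1, NA, NA, NA, NA, NA, NA)
      addRow("CA", 1, at(1, "N"), NA, NA, G$CA$length, NA, NA)
      addRow("C", 1, at(1, "CA"), at(1, "N"), NA, G$C$length, G$C$angle, NA)
    } else {
      # N(i): dihedral psi(i-1); CA(i): omega = 180; C(i): phi(i)
      addRow("N", i, at(i - 1, "C"), at(i - 1, "CA"), at(i - 1, "N"),
             G$N$length, G$N$angle, wrapAngle(pp[i - 1, 2]))
      addRow("CA", i, at(i, "N"), at(i - 1, "C"), at(i - 1, "CA"),
             G$CA$length, G$CA$angle, 180)
      addRow("C", i, at(i, "CA"), at(i, "N"), at(i - 1, "C"),
             G$C$length, G$C$angle, wrapAngle(phi))
    }
    # O(i): anti-periplanar to the next N, i.e. psi(i) + 180
    addRow("O", i, at(i, "C"), at(i, "CA"), at(i, "N"),
           G$O$length, G$O$angle, wrapAngle(psi + 180))
    if (resnames[i] != "GLY") {
      gg <- if (i == 1) at(1, "C") else at(i - 1, "C")
      dih <- if (i == 1) -122.6 else wrapAngle(phi - 122.6)
      addRow("CB", i, at(i, "CA"), at(i, "N"), gg,
             G$CB$length, G$CB$angle, dih)
    }
  }
  tab <- do.call(rbind, rows)
  if (lengthSd > 0 || angleSd > 0) {
    hasLen <- !is.na(tab$length); hasAng <- !is.na(tab$angle)
    jit <- withSeed(seed + 7919L, list(
      len = stats::rnorm(sum(hasLen), sd = lengthSd),
      ang = stats::rnorm(sum(hasAng), sd = angleSd)))
    tab$length[hasLen] <- pmax(0.9, tab$length[hasLen] + jit$len)
    tab$angle[hasAng] <- pmin(175, pmax(5, tab$angle[hasAng] + jit$ang))
  }
  ic <- new("InternalCoordinates", table = tab)
  atoms <- rebuildPeptide(ic, "measured")
  atoms$chain <- chain
  atoms
}

#' Build a toy protein-peptide complex with known contacts
#'
#' Generates a helical receptor chain of the requested size and places
#' the given peptide against its surface so that the interface has at
#' least one (and typically several) residue contacts at the 5 A cutoff.
#' The exact native \linkS4class{ContactSet} is returned alongside the
#' complex.
#'
#' @param receptorSize number of receptor residues (>= 3).
#' @param peptide peptide atom data.frame (e.g. from
#'   \code{\link{makePeptide}}); if \code{NULL}, a seeded 10-mer helix.
#' @param seed integer seed controlling the receptor sequence and the
#'   placement direction.
#' @param cutoff contact cutoff (A).
#' @param minContacts minimum number of residue contacts the placement
#'   must achieve.
#' @param pdbId identifier for the complex.
#' @param maxAttempts placement attempts before giving up.
#' @return list with \code{complex} (a \linkS4class{PeptideComplex}) and
#'   \code{contacts} (its native \linkS4class{ContactSet}).
#' @export
makeToyComplex <- function(receptorSize = 30L, peptide = NULL, seed = 1L,
                           cutoff = 5.0, minContacts = 3L,
                           pdbId = sprintf("TOY%04d", seed),
                           maxAttempts = 50L) {
  stopifnot(receptorSize >= 3)
  aa <- names(AA_1TO3)[!names(AA_1TO3) %in% c("G", "P")]
  recSeq <- withSeed(seed, paste(sample(aa, receptorSize, replace = TRUE),
                                 collapse = ""))
  receptor <- makePeptide(recSeq, "helix", chain = "A")
  if (is.null(peptide)) {
    pepSeq <- withSeed(seed + 1L,
                       paste(sample(aa, 10, replace = TRUE), collapse = ""))
    peptide <- makePeptide(pepSeq, "helix", seed = seed + 1L, chain = "B")
  }
  peptide$chain <- "B"
  recXyz <- coordMatrix(receptor[isHeavy(receptor), , drop = FALSE])
  pepXyz0 <- coordMatrix(peptide[isHeavy(peptide), , drop = FALSE])
  pepCentroid <- colMeans(pepXyz0)
  pepRadius <- sqrt(max(rowSums(sweep(pepXyz0, 2, pepCentroid)^2)))
  cx <- NULL
  withSeed(seed + 2L, {
    for (attempt in seq_len(maxAttempts)) {
      R <- randomRotation()
      u <- unitVec(stats::rnorm(3))
      proj <- recXyz %*% u
      surf <- recXyz[which.max(proj), ]
      pepRot <- sweep(pepXyz0, 2, pepCentroid) %*% t(R)
      # slide the peptide in along -u until it touches the receptor
      placed <- NULL
      for (d in seq(pepRadius + 10, 0, by = -0.2)) {
        cand <- sweep(pepRot, 2, surf + d * u, "+")
        mind <- sqrt(max(0, min(
          outer(rowSums(cand^2), rowSums(recXyz^2), "+") -
            2 * cand %*% t(recXyz))))
        if (mind < 2.6) break
        if (mind <= 3.6) { placed <- cand; break }
      }
      if (is.null(placed)) next
      pep <- setCoords(peptide[isHeavy(peptide), , drop = FALSE], placed)
      cand <- PeptideComplex(pdbId = pdbId,
                             receptor = receptor, peptide = pep,
                             receptorChain = "A", peptideChain = "B")
      cs <- residueContacts(cand, cutoff)
      if (length(cs) >= minContacts) {
        cx <- list(complex = cand, contacts = cs)
        break
      }
    }
  })
  if (is.null(cx))
    stop(sprintf("failed to place the peptide in %d attempts", maxAttempts))
  cx
}

#' Specification of one synthetic decoy pose
#'
#' @param transform a \linkS4class{RigidTransform} applied to the native
#'   peptide (receptor fixed), or \code{NULL} for identity.
#' @param dihedralNoise standard deviation (degrees) of Gaussian noise
#'   added to every internal dihedral.
#' @param coordNoise standard deviation (A) of Gaussian coordinate
#'   noise.
#' @param seed integer seed for the noise.
#' @return a \code{DecoySpec} list.
#' @export
decoySpec <- function(transform = NULL, dihedralNoise = 0, coordNoise = 0,
                      seed = 1L) {
  stopifnot(dihedralNoise >= 0, coordNoise >= 0)
  structure(list(transform = transform, dihedralNoise = dihedralNoise,
                 coordNoise = coordNoise, seed = as.integer(seed)),
            class = "DecoySpec")
}

#' Generate ranked decoy poses from a native complex
#'
#' Each decoy applies its spec (dihedral noise, coordinate noise, rigid
#' transform — in that order) to the native peptide while the receptor
#' stays fixed. For pure-rigid decoys (no noise) the analytic L-RMSD
#' implied by the transform acting on the peptide backbone coordinates
#' is recorded as ground truth.
#'
#' @param native a \linkS4class{PeptideComplex}.
#' @param specs list of \code{\link{decoySpec}} objects; decoy ranks
#'   follow list order.
#' @param method method label stored on the models.
#' @return list with \code{models} (list of
#'   \linkS4class{PeptideComplex}) and \code{groundTruth} (data.frame
#'   with \code{rank} and \code{analytic_l_rmsd}, NA for non-rigid
#'   decoys).
#' @export
makeDecoys <- function(native, specs, method = "synthetic") {
  stopifnot(length(specs) >= 1)
  pep0 <- peptideAtoms(native)
  bb0 <- backboneAtoms(pep0)$xyz
  models <- vector("list", length(specs))
  analytic <- rep(NA_real_, length(specs))
  for (r in seq_along(specs)) {
    sp <- specs[[r]]
    pep <- pep0
    pure <- sp$dihedralNoise == 0 && sp$coordNoise == 0
    if (sp$dihedralNoise > 0) {
      ic <- toInternal(pep)
      tb <- icTable(ic)
      rowsFull <- which(!is.na(tb$dihedral))
      tb$dihedral[rowsFull] <- withSeed(sp$seed, wrapAngle(
        tb$dihedral[rowsFull] +
          stats::rnorm(length(rowsFull), sd = sp$dihedralNoise)))
      rebuilt <- rebuildPeptide(new("InternalCoordinates", table = tb),
                                "measured")
      rebuilt$chain <- pep$chain[1]
      # put the perturbed conformation back at the binding site
      fit <- superpose(backboneAtoms(rebuilt)$xyz, backboneAtoms(pep)$xyz)
      rebuilt <- setCoords(rebuilt,
                           applyTransform(fit$transform, coordMatrix(rebuilt)))
      pep <- rebuilt
    }
    if (sp$coordNoise > 0) {
      xyz <- coordMatrix(pep)
      noise <- withSeed(sp$seed + 104729L,
                        matrix(stats::rnorm(length(xyz), sd = sp$coordNoise),
                               ncol = 3))
      pep <- setCoords(pep, xyz + noise)
    }
    if (!is.null(sp$transform)) {
      pep <- setCoords(pep, applyTransform(sp$transform, coordMatrix(pep)))
      if (pure)
        analytic[r] <- rmsdNoFit(applyTransform(sp$transform, bb0), bb0)
    } else if (pure) analytic[r] <- 0
    models[[r]] <- PeptideComplex(
      pdbId = pdbId(native), receptor = receptorAtoms(native), peptide = pep,
      receptorChain = native@receptorChain, peptideChain = native@peptideChain,
      resolution = resolution(native))
  }
  list(models = models,
       groundTruth = data.frame(rank = seq_along(specs),
                                analytic_l_rmsd = analytic))
}
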