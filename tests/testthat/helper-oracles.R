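# Independent oracles used to check the package's computations.
# Everything here deliberately avoids the code paths under test:
# contacts by nested loops, superposition by rotation sampling plus
# Nelder-Mead refinement over axis-angle parameters (no SVD), torsions
# via bio3d.

heavyOnly <- function(atoms) {
  atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
}

resKeyOf <- function(atoms) {
  paste0(atoms$resno, ifelse(nzchar(atoms$insert), atoms$insert, ""),
         ":", atoms$resname)
}

# O(n^2) contact enumeration: every heavy-atom pair, nested loops.
bruteContactPairs <- function(cx, cutoff = 5.0) {
  rec <- heavyOnly(receptorAtoms(cx))
  pep <- heavyOnly(peptideAtoms(cx))
  rk <- resKeyOf(rec); pk <- resKeyOf(pep)
  out <- character()
  for (r in unique(rk)) {
    ra <- as.matrix(rec[rk == r, c("x", "y", "z")])
    for (p in unique(pk)) {
      pa <- as.matrix(pep[pk == p, c("x", "y", "z")])
      dmin <- Inf
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(pa)))
        dmin <- min(dmin, sqrt(sum((ra[i, ] - pa[j, ])^2)))
      if (dmin <= cutoff) out <- c(out, paste(r, p, sep = "+"))
    }
  }
  sort(out)
}

contactKeys <- function(cs) {
  p <- contactPairs(cs)
  sort(paste(p$receptor, p$peptide, sep = "+"))
}

rodrigues <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# RMSD of mobile onto reference for a fixed rotation, with the optimal
# translation (centroid alignment).
rotRmsd <- function(R, mobile, reference) {
  rm <- mobile %*% t(R)
  rm <- sweep(rm, 2, colMeans(rm))
  rf <- sweep(reference, 2, colMeans(reference))
  sqrt(sum((rm - rf)^2) / nrow(mobile))
}

# Rotation-sampling + Nelder-Mead oracle for the minimal superposition
# RMSD; returns list(rmsd, rotation). No SVD anywhere.
oracleSuperpose <- function(mobile, reference, nSamples = 2000) {
  best <- NULL; bestVal <- Inf
  for (i in seq_len(nSamples)) {
    ax <- stats::rnorm(3); ang <- stats::runif(1, 0, pi)
    R <- rodrigues(ax, ang)
    v <- rotRmsd(R, mobile, reference)
    if (v < bestVal) { bestVal <- v; best <- c(ax / sqrt(sum(ax^2)) * ang) }
  }
  obj <- function(p) rotRmsd(rodrigues(p, sqrt(sum(p^2)) + 1e-12), mobile,
                             reference)
  objAA <- function(p) {
    ang <- sqrt(sum(p^2))
    if (ang < 1e-12) return(rotRmsd(diag(3), mobile, reference))
    rotRmsd(rodrigues(p / ang, ang), mobile, reference)
  }
  for (k in 1:3) {
    op <- stats::optim(best, objAA, method = "Nelder-Mead",
                       control = list(reltol = 1e-16, maxit = 5000))
    best <- op$par
  }
  ang <- sqrt(sum(best^2))
  R <- if (ang < 1e-12) diag(3) else rodrigues(best / ang, ang)
  list(rmsd = objAA(best), rotation = R)
}

# Oracle L-RMSD: fit the receptor by rotation sampling (independent of
# the package's Kabsch), then carry the fitted transform onto the
# peptide.
oracleLrmsd <- function(native, model, nSamples = 2000) {
  recN <- backboneAtoms(receptorAtoms(native))$xyz
  recM <- backboneAtoms(receptorAtoms(model))$xyz
  pepN <- backboneAtoms(peptideAtoms(native))$xyz
  pepM <- backboneAtoms(peptideAtoms(model))$xyz
  or <- oracleSuperpose(recM, recN)
  R <- or$rotation
  t <- colMeans(recN) - colMeans(recM %*% t(R))
  fitted <- sweep(pepM %*% t(R), 2, t, "+")
  sqrt(sum((fitted - pepN)^2) / nrow(pepN))
}

# Oracle I-RMSD (interface frame): minimal RMSD over rotations of the
# paired interface backbone atoms.
oracleIrmsd <- function(native, model, cutoff = 5.0, nSamples = 2000) {
  iface <- interfaceResidues(native, cutoff)
  pick <- function(cx) {
    rec <- receptorAtoms(cx); pep <- peptideAtoms(cx)
    rbind(backboneAtoms(rec[resKeyOf(rec) %in% iface$receptor, ])$xyz,
          backboneAtoms(pep[resKeyOf(pep) %in% iface$peptide, ])$xyz)
  }
  oracleSuperpose(pick(model), pick(native))$rmsd
}

# A seeded pool of toy complexes shared by several tests.
toyComplexPool <- function(seeds, receptorSize = 24L) {
  lapply(seeds, function(s) makeToyComplex(receptorSize, seed = s))
}

# Minimal hand-built atom table.
atomRows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(eleno = i, elety = r$elety, resname = r$resname,
               chain = r$chain %||% "A", resno = r$resno,
               insert = r$insert %||% "",
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               element = r$element %||% substr(r$elety, 1, 1),
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

at <- function(elety, resname, resno, xyz, chain = "A", insert = "",
               element = NULL) {
  list(elety = elety, resname = resname, resno = resno, xyz = xyz,
       chain = chain, insert = insert, element = element)
}

coordsOf <- function(atoms) unname(as.matrix(atoms[, c("x", "y", "z")]))

transformAtoms <- function(atoms, tr) {
  xyz <- applyTransform(tr, as.matrix(atoms[, c("x", "y", "z")]))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# Circular angle difference in degrees.
circDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
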