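# metrics: the CAPRI-parameter core — residue contacts, FNAT, L-RMSD,
# I-RMSD, B-RMSD and binding-site extraction.
#
# Conventions (all configurable where noted):
#   * contacts use heavy atoms only, cutoff inclusive at the boundary;
#   * backbone = {N, CA, C, O} by default ({N, CA, C} available);
#   * native and model residues are paired strictly by residue key
#     (number + insertion code + name); a mismatch is an error, never a
#     silent intersection. Missing atoms within a matched residue are
#     skipped so selections stay aligned.

# Strict residue-level pairing, atom-level intersection in native order.
pairedXyz <- function(natSel, modSel, what) {
  natRes <- unique(natSel$resKey); modRes <- unique(modSel$resKey)
  if (length(natRes) != length(modRes) || !all(natRes == modRes))
    stop(sprintf(
      "%s residues do not pair between native and model (native: %d, model: %d residues)",
      what, length(natRes), length(modRes)))
  common <- intersect(natSel$key, modSel$key)
  if (!length(common))
    stop(sprintf("%s selections share no atoms", what))
  list(native = natSel$xyz[match(common, natSel$key), , drop = FALSE],
       model = modSel$xyz[match(common, modSel$key), , drop = FALSE])
}

# Minimum heavy-atom distance between every receptor/peptide residue pair.
residueMinDistances <- function(x) {
  rec <- heavyAtoms(receptorAtoms(x))
  pep <- heavyAtoms(peptideAtoms(x))
  r <- rec$xyz; p <- pep$xyz
  D2 <- outer(rowSums(r^2), rowSums(p^2), "+") - 2 * (r %*% t(p))
  D2[D2 < 0] <- 0
  recFac <- factor(rec$resKey, levels = unique(rec$resKey))
  pepFac <- factor(pep$resKey, levels = unique(pep$resKey))
  recLevels <- levels(recFac); pepLevels <- levels(pepFac)
  out <- matrix(NA_real_, length(recLevels), length(pepLevels),
                dimnames = list(recLevels, pepLevels))
  for (i in seq_along(recLevels)) {
    sub <- D2[recFac == recLevels[i], , drop = FALSE]
    colMin <- apply(sub, 2, min)
    out[i, ] <- as.vector(tapply(colMin, pepFac, min))
  }
  sqrt(out)
}

#' Residue-residue contacts across the protein-peptide interface
#'
#' A receptor residue and a peptide residue are in contact when the
#' minimum distance between their heavy atoms is within the cutoff
#' (inclusive; default 5 A).
#'
#' @param x a \linkS4class{PeptideComplex}.
#' @param cutoff contact cutoff in Angstrom.
#' @return a \linkS4class{ContactSet} (possibly empty).
#' @export
residueContacts <- function(x, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  md <- residueMinDistances(x)
  hit <- which(md <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(
    receptor = rownames(md)[hit[, 1]],
    peptide = colnames(md)[hit[, 2]],
    minDist = md[hit],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(hit[, 1], hit[, 2]), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ContactSet", pairs = pairs, cutoff = cutoff)
}

checkResiduePairing <- function(native, model) {
  for (side in c("receptor", "peptide")) {
    a <- residueOrder(slot(native, side))
    b <- residueOrder(slot(model, side))
    if (length(a) != length(b) || !all(a == b))
      stop(sprintf("%s residues of native and model do not pair one-to-one",
                   side))
  }
  invisible(TRUE)
}

#' Fraction of native contacts (FNAT)
#'
#' The number of native residue-residue contacts recovered in the
#' predicted complex divided by the number of residue-residue contacts
#' in the native complex. Contacts present only in the model are
#' ignored.
#'
#' @param native,model \linkS4class{PeptideComplex} objects with
#'   one-to-one pairable residues.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fraction in [0, 1].
#' @export
computeFnat <- function(native, model, cutoff = 5.0) {
  checkResiduePairing(native, model)
  nat <- residueContacts(native, cutoff)
  if (!length(nat))
    stop(sprintf(
      "complex '%s' has no native contacts at %.1f A; FNAT is undefined (such complexes are excluded from benchmarking)",
      pdbId(native), cutoff))
  mod <- residueContacts(model, cutoff)
  natKeys <- paste(nat@pairs$receptor, nat@pairs$peptide, sep = "+")
  modKeys <- paste(mod@pairs$receptor, mod@pairs$peptide, sep = "+")
  sum(natKeys %in% modKeys) / length(natKeys)
}

#' Ligand RMSD (L-RMSD)
#'
#' Backbone RMSD of the peptide between native and model after
#' superposing the model receptor backbone onto the native receptor
#' backbone. The fitted transform is applied to the model peptide and the
#' RMSD is taken without re-fitting the peptide.
#'
#' @inheritParams computeFnat
#' @param convention backbone convention, \code{"NCACO"} or
#'   \code{"NCAC"}.
#' @return L-RMSD in Angstrom.
#' @export
computeLrmsd <- function(native, model, convention = "NCACO") {
  checkResiduePairing(native, model)
  rec <- pairedXyz(backboneAtoms(receptorAtoms(native), convention),
                   backboneAtoms(receptorAtoms(model), convention),
                   "receptor backbone")
  pep <- pairedXyz(backboneAtoms(peptideAtoms(native), convention),
                   backboneAtoms(peptideAtoms(model), convention),
                   "peptide backbone")
  fit <- superpose(rec$model, rec$native)
  rmsdNoFit(applyTransform(fit$transform, pep$model), pep$native)
}

#' Interface residues of the native complex
#'
#' Residues of either chain appearing in any native contact pair; defined
#' on the native complex only.
#'
#' @inheritParams residueContacts
#' @return list with \code{receptor} and \code{peptide} residue-key
#'   vectors.
#' @export
interfaceResidues <- function(x, cutoff = 5.0) {
  cs <- residueContacts(x, cutoff)
  if (!length(cs))
    stop(sprintf("complex '%s' has no native contacts at %.1f A",
                 pdbId(x), cutoff))
  list(receptor = unique(cs@pairs$receptor),
       peptide = unique(cs@pairs$peptide))
}

selectResidues <- function(atoms, keys) {
  atoms[residueKeys(atoms) %in% keys, , drop = FALSE]
}

#' Interface RMSD (I-RMSD)
#'
#' Backbone RMSD over the native interface residues (both sides) between
#' native and model. By default the fit frame is the interface itself:
#' the paired interface backbone atoms are optimally superposed and the
#' post-fit RMSD is returned. With \code{fitFrame = "receptor"} the
#' transform is instead fitted on the full receptor backbone.
#'
#' @inheritParams computeLrmsd
#' @param cutoff interface definition cutoff in Angstrom (default 5).
#' @param fitFrame \code{"interface"} (default) or \code{"receptor"}.
#' @return I-RMSD in Angstrom.
#' @export
computeIrmsd <- function(native, model, cutoff = 5.0,
                         convention = "NCACO",
                         fitFrame = c("interface", "receptor")) {
  fitFrame <- match.arg(fitFrame)
  checkResiduePairing(native, model)
  iface <- interfaceResidues(native, cutoff)
  natSel <- rbind2sel(
    backboneAtoms(selectResidues(receptorAtoms(native), iface$receptor),
                  convention),
    backboneAtoms(selectResidues(peptideAtoms(native), iface$peptide),
                  convention))
  modSel <- rbind2sel(
    backboneAtoms(selectResidues(receptorAtoms(model), iface$receptor),
                  convention),
    backboneAtoms(selectResidues(peptideAtoms(model), iface$peptide),
                  convention))
  pr <- pairedXyz(natSel, modSel, "interface backbone")
  if (nrow(pr$native) < 3)
    stop("degenerate geometry: fewer than 3 paired interface backbone atoms")
  if (fitFrame == "interface") {
    superpose(pr$model, pr$native)$rmsd
  } else {
    rec <- pairedXyz(backboneAtoms(receptorAtoms(native), convention),
                     backboneAtoms(receptorAtoms(model), convention),
                     "receptor backbone")
    fit <- superpose(rec$model, rec$native)
    rmsdNoFit(applyTransform(fit$transform, pr$model), pr$native)
  }
}

# Concatenate two selection lists (receptor side first).
rbind2sel <- function(a, b) {
  list(xyz = rbind(a$xyz, b$xyz),
       key = c(paste0("R:", a$key), paste0("P:", b$key)),
       resKey = c(paste0("R:", a$resKey), paste0("P:", b$resKey)))
}

#' Backbone RMSD between two conformations of one peptide (B-RMSD)
#'
#' Position-independent conformation comparison: the rebuilt peptide
#' backbone is optimally superposed onto the original and the post-fit
#' RMSD is returned. Used to verify that coordinate shifting does not
#' change the peptide structure.
#'
#' @param original,rebuilt peptide atom data.frames with the same residue
#'   count and names.
#' @param convention backbone convention.
#' @return B-RMSD in Angstrom.
#' @export
computeBrmsd <- function(original, rebuilt, convention = "NCACO") {
  ra <- residueOrder(original); rb <- residueOrder(rebuilt)
  if (length(ra) != length(rb) ||
      !all(sub(".*:", "", ra) == sub(".*:", "", rb)))
    stop("peptides differ in residue count or names")
  a <- backboneAtoms(original, convention)
  b <- backboneAtoms(rebuilt, convention)
  # pair positionally: same residue rank + atom name (numbering may differ)
  rankA <- match(a$resKey, unique(a$resKey))
  rankB <- match(b$resKey, unique(b$resKey))
  keyA <- paste0(rankA, "|", sub(".*\\|", "", a$key))
  keyB <- paste0(rankB, "|", sub(".*\\|", "", b$key))
  common <- intersect(keyA, keyB)
  if (length(common) < 3) stop("fewer than 3 paired backbone atoms")
  superpose(b$xyz[match(common, keyB), , drop = FALSE],
            a$xyz[match(common, keyA), , drop = FALSE])$rmsd
}

#' Receptor binding-site residues
#'
#' Receptor residues with at least one heavy atom within the cutoff of
#' any peptide heavy atom, in receptor residue order. This is the
#' binding-site list supplied to re-docking runs.
#'
#' @inheritParams residueContacts
#' @return character vector of receptor residue keys (possibly empty,
#'   with a warning).
#' @export
bindingSiteResidues <- function(x, cutoff = 5.0) {
  md <- residueMinDistances(x)
  keys <- rownames(md)[apply(md <= cutoff, 1, any)]
  if (!length(keys))
    warning(sprintf("no receptor residue within %.1f A of the peptide",
                    cutoff), call. = FALSE)
  keys
}

#' Evaluate one docked pose against the native complex
#'
#' Bundles FNAT, L-RMSD and I-RMSD computed with a shared residue pairing
#' and shared cutoffs into a \linkS4class{PoseEvaluation}. Errors from a
#' component metric are re-raised labelled with the metric name.
#'
#' @inheritParams computeFnat
#' @param convention backbone convention.
#' @param rank,method metadata stored in the result.
#' @return a \linkS4class{PoseEvaluation}.
#' @export
evaluatePose <- function(native, model, cutoff = 5.0, convention = "NCACO",
                         rank = 1L, method = "unknown") {
  wrap <- function(metric, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", metric, conditionMessage(e)), call. = FALSE))
  f <- wrap("FNAT", computeFnat(native, model, cutoff))
  l <- wrap("L-RMSD", computeLrmsd(native, model, convention))
  i <- wrap("I-RMSD", computeIrmsd(native, model, cutoff, convention))
  PoseEvaluation(fnat = f, lRmsd = l, iRmsd = i, rank = rank, method = method)
}
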