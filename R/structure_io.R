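# structure_io: reading, cleaning, validating and writing PDB complexes.
#
# Cleaning rules applied on read:
#   * hetero-atoms (HETATM records: waters, metal ions, ...) are removed;
#   * when an atom has alternate locations, only the 'A' coordinates are
#     kept;
#   * residues whose name is not one of the 20 standard amino acids are
#     rejected (modified residues invalidate a benchmark complex);
#   * hydrogens are retained but flagged by element and excluded from all
#     metric computations.

bio3dToAtoms <- function(atomDf, xyz = NULL) {
  df <- data.frame(
    eleno = atomDf$eleno,
    elety = trimws(atomDf$elety),
    resname = trimws(atomDf$resid),
    chain = ifelse(is.na(atomDf$chain), "", atomDf$chain),
    resno = atomDf$resno,
    insert = ifelse(is.na(atomDf$insert), "", atomDf$insert),
    x = atomDf$x, y = atomDf$y, z = atomDf$z,
    stringsAsFactors = FALSE)
  if (!is.null(xyz)) {
    df$x <- xyz[seq(1, length(xyz), 3)]
    df$y <- xyz[seq(2, length(xyz), 3)]
    df$z <- xyz[seq(3, length(xyz), 3)]
  }
  elesy <- if ("elesy" %in% colnames(atomDf)) trimws(atomDf$elesy) else NA
  elesy[is.na(elesy) | !nzchar(elesy)] <-
    elementFromName(df$elety[is.na(elesy) | !nzchar(elesy)])
  df$element <- toupper(elesy)
  rownames(df) <- NULL
  df
}

extractChain <- function(atoms, chain, path) {
  sel <- atoms[atoms$chain == chain, , drop = FALSE]
  if (!nrow(sel)) {
    avail <- sort(unique(atoms$chain))
    stop(sprintf("chain '%s' not found in '%s' (available polymer chains: %s)",
                 chain, path, paste(avail, collapse = ", ")))
  }
  bad <- setdiff(unique(sel$resname), STANDARD_AA)
  if (length(bad))
    stop(sprintf("chain '%s' of '%s' contains modified/non-standard residues: %s",
                 chain, path, paste(bad, collapse = ", ")))
  rownames(sel) <- NULL
  sel
}

# Parse "REMARK   2 RESOLUTION.  1.55 ANGSTROMS" if present.
parseResolution <- function(path) {
  ln <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE),
             value = TRUE)
  if (!length(ln)) return(NA_real_)
  m <- regmatches(ln[1], regexpr("[0-9]+\\.[0-9]+", ln[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

checkPeptideLength <- function(atoms, what = "peptide") {
  n <- length(residueOrder(atoms))
  if (n < 9 || n > 15)
    warning(sprintf(
      "%s has %d residues, outside the benchmark range [9, 15]", what, n),
      call. = FALSE)
  n
}

#' Read and clean a protein-peptide complex from a PDB file
#'
#' Parses a PDB file, applies the dataset cleaning rules (drop
#' hetero-atoms and waters, keep only 'A' alternate locations, reject
#' modified residues) and returns the receptor and peptide chains as a
#' \linkS4class{PeptideComplex}. A warning is issued when the peptide
#' length falls outside the benchmark range of 9 to 15 residues.
#'
#' @param path PDB file path.
#' @param receptorChain,peptideChain single-letter chain identifiers.
#' @param pdbId identifier stored in the result; defaults to the file
#'   base name.
#' @param resolution crystallographic resolution (A); when \code{NULL}
#'   the REMARK 2 record is parsed if present.
#' @return a \linkS4class{PeptideComplex}.
#' @examples
#' pdb <- system.file("extdata", "toy_complex.pdb", package = "PepDockBench")
#' cx <- readComplex(pdb, receptorChain = "A", peptideChain = "B")
#' cx
#' @export
readComplex <- function(path, receptorChain, peptideChain,
                        pdbId = NULL, resolution = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  pdb <- bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
  atoms <- bio3dToAtoms(pdb$atom)
  polymer <- atoms[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(polymer))
    stop(sprintf("'%s' contains no polymer (ATOM) records", path))
  rec <- extractChain(polymer, receptorChain, path)
  pep <- extractChain(polymer, peptideChain, path)
  checkPeptideLength(pep)
  if (is.null(resolution)) resolution <- parseResolution(path)
  if (is.null(pdbId)) pdbId <- sub("\\.(pdb|ent)$", "", basename(path))
  PeptideComplex(pdbId = pdbId, receptor = rec, peptide = pep,
                 receptorChain = receptorChain, peptideChain = peptideChain,
                 resolution = resolution)
}

#' Read a multi-model PDB file as a ranked list of docked poses
#'
#' Each MODEL record is treated as one docked pose; poses are ranked by
#' file order.
#'
#' @inheritParams readComplex
#' @return a list of \linkS4class{PeptideComplex}, one per MODEL.
#' @export
readPoses <- function(path, receptorChain, peptideChain, pdbId = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (is.null(pdbId)) pdbId <- sub("\\.(pdb|ent)$", "", basename(path))
  lapply(seq_len(nmod), function(i) {
    atoms <- bio3dToAtoms(pdb$atom, xyz = pdb$xyz[i, ])
    polymer <- atoms[pdb$atom$type == "ATOM", , drop = FALSE]
    if (!nrow(polymer))
      stop(sprintf("'%s' contains no polymer (ATOM) records", path))
    rec <- extractChain(polymer, receptorChain, path)
    pep <- extractChain(polymer, peptideChain, path)
    PeptideComplex(pdbId = sprintf("%s#%d", pdbId, i),
                   receptor = rec, peptide = pep,
                   receptorChain = receptorChain,
                   peptideChain = peptideChain)
  })
}

#' Write a complex to a PDB file
#'
#' Emits standard ATOM records with sequentially renumbered atom serials;
#' chain identifiers, residue numbering and insertion codes are
#' preserved. Coordinates round-trip through \code{\link{readComplex}} to
#' the fixed-format precision of 1e-3 A.
#'
#' @param x a \linkS4class{PeptideComplex}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeComplex <- function(x, path) {
  atoms <- rbind(x@receptor, x@peptide)
  xyz <- as.vector(t(coordMatrix(atoms)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno,
                   resid = atoms$resname,
                   insert = ifelse(nzchar(atoms$insert), atoms$insert, ""),
                   chain = atoms$chain,
                   elety = atoms$elety,
                   eleno = seq_len(nrow(atoms)),
                   elesy = atoms$element,
                   o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)))
  invisible(path)
}

#' Write a set of docked poses as a multi-model PDB file
#'
#' @param poses list of \linkS4class{PeptideComplex} sharing one topology.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePoses <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(poses)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    tmp <- tempfile(fileext = ".pdb")
    writeComplex(poses[[i]], tmp)
    body <- readLines(tmp)
    unlink(tmp)
    writeLines(body[!grepl("^END", body)], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Backbone atom selection with pairing keys
#'
#' Selects the backbone atoms (by default N, CA, C, O in that order per
#' residue) from an atom table. Missing backbone atoms are skipped so
#' that native and model selections can be aligned by their pairing keys;
#' a residue contributing zero backbone atoms triggers a warning and is
#' skipped.
#'
#' @param atoms atom data.frame (a \code{receptorAtoms()} or
#'   \code{peptideAtoms()} table).
#' @param convention \code{"NCACO"} (default, includes the carbonyl
#'   oxygen) or \code{"NCAC"}.
#' @return list with \code{xyz} (n x 3 matrix), \code{key} (character,
#'   "residueKey|atomName") and \code{resKey} (character).
#' @export
backboneAtoms <- function(atoms, convention = c("NCACO", "NCAC")) {
  convention <- match.arg(convention)
  names <- if (convention == "NCACO") c("N", "CA", "C", "O")
           else c("N", "CA", "C")
  stopifnot(nrow(atoms) > 0)
  keys <- residueKeys(atoms)
  out <- vector("list", length(unique(keys)))
  i <- 0
  for (rk in residueOrder(atoms)) {
    res <- atoms[keys == rk, , drop = FALSE]
    hit <- res[match(names, res$elety, nomatch = 0), , drop = FALSE]
    if (!nrow(hit)) {
      warning(sprintf("residue %s has no backbone atoms; skipped", rk),
              call. = FALSE)
      next
    }
    i <- i + 1
    out[[i]] <- hit
  }
  sel <- do.call(rbind, out[seq_len(i)])
  list(xyz = coordMatrix(sel),
       key = paste0(residueKeys(sel), "|", sel$elety),
       resKey = residueKeys(sel))
}

#' Heavy atom selection with pairing keys
#'
#' All non-hydrogen atoms in original order, keyed by residue and atom
#' name.
#'
#' @inheritParams backboneAtoms
#' @return list with \code{xyz}, \code{key} and \code{resKey} as in
#'   \code{\link{backboneAtoms}}.
#' @export
heavyAtoms <- function(atoms) {
  stopifnot(nrow(atoms) > 0)
  sel <- atoms[isHeavy(atoms), , drop = FALSE]
  list(xyz = coordMatrix(sel),
       key = paste0(residueKeys(sel), "|", sel$elety),
       resKey = residueKeys(sel))
}
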