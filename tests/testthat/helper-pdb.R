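# Programmatic PDB fixture text (no stored binary fixtures).

pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z,
                        altloc = " ", insert = " ", occ = 1.0, b = 0.0,
                        element = NULL, het = FALSE) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, altloc, resname,
          chain, resno, insert, x, y, z, occ, b, element)
}

# A small two-chain complex: receptor chain A (glycine-like backbones on
# a line) and peptide chain B nearby, with optional decorations.
writeFixturePdb <- function(path, nRec = 5, nPep = 3,
                            withWater = FALSE, withIon = FALSE,
                            withAltloc = FALSE, withHydrogen = FALSE,
                            withInsert = FALSE, modifiedResidue = FALSE) {
  ln <- character(); s <- 0
  bb <- function(resno, ox, oy, chain, resname = "GLY", insert = " ") {
    c(pdbAtomLine(s + 1, "N", resname, chain, resno, ox, oy, 0.0,
                  insert = insert),
      pdbAtomLine(s + 2, "CA", resname, chain, resno, ox + 1.2, oy + 0.8, 0.3),
      pdbAtomLine(s + 3, "C", resname, chain, resno, ox + 2.4, oy, 0.1),
      pdbAtomLine(s + 4, "O", resname, chain, resno, ox + 2.5, oy - 1.2, 0.2))
  }
  for (i in seq_len(nRec)) {
    rn <- if (modifiedResidue && i == 2) "MSE" else "GLY"
    ln <- c(ln, bb(i, 3.5 * (i - 1), 0, "A", rn)); s <- s + 4
  }
  if (withAltloc) {
    ln <- c(ln,
            pdbAtomLine(s + 1, "CB", "ALA", "A", nRec + 1, 0.0, 3.0, 0.0,
                        altloc = "A", occ = 0.6),
            pdbAtomLine(s + 2, "CB", "ALA", "A", nRec + 1, 9.9, 9.9, 9.9,
                        altloc = "B", occ = 0.4),
            pdbAtomLine(s + 3, "N", "ALA", "A", nRec + 1, 0.5, 3.5, 0.2),
            pdbAtomLine(s + 4, "CA", "ALA", "A", nRec + 1, 1.0, 3.2, 0.4),
            pdbAtomLine(s + 5, "C", "ALA", "A", nRec + 1, 2.2, 3.9, 0.2),
            pdbAtomLine(s + 6, "O", "ALA", "A", nRec + 1, 2.4, 5.0, 0.6))
    s <- s + 6
  }
  for (j in seq_len(nPep)) {
    ins <- if (withInsert && j == 2) "A" else " "
    resno <- if (withInsert && j >= 2) j - 1 else j
    ln <- c(ln, bb(resno, 3.5 * (j - 1), 4.5, "B", insert = ins)); s <- s + 4
  }
  if (withHydrogen) {
    ln <- c(ln, pdbAtomLine(s + 1, "H", "GLY", "B", 1, 0.1, 5.2, 0.5,
                            element = "H"))
    s <- s + 1
  }
  if (withWater) {
    ln <- c(ln, pdbAtomLine(s + 1, "O", "HOH", "A", 900, 20, 20, 20,
                            het = TRUE))
    s <- s + 1
  }
  if (withIon) {
    ln <- c(ln, pdbAtomLine(s + 1, "ZN", "ZN", "A", 901, 21, 21, 21,
                            element = "ZN", het = TRUE))
    s <- s + 1
  }
  writeLines(c(ln, "END"), path)
  invisible(path)
}
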