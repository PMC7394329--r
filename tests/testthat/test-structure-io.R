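test_that("reading applies the dataset cleaning rules", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeFixturePdb(f, nRec = 5, nPep = 3, withWater = TRUE, withIon = TRUE,
                  withAltloc = TRUE, withHydrogen = TRUE)
  cx <- suppressWarnings(readComplex(f, "A", "B"))
  rec <- receptorAtoms(cx); pep <- peptideAtoms(cx)
  # hetero-atoms (water, ion) gone
  expect_false(any(rec$resname %in% c("HOH", "ZN")))
  expect_false(any(pep$resname %in% c("HOH", "ZN")))
  # only the altloc 'A' CB survives, with its 'A' coordinates
  cb <- rec[rec$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(unlist(cb[, c("x", "y", "z")], use.names = FALSE),
               c(0.0, 3.0, 0.0))
  # hydrogen retained but excluded from the heavy-atom selection
  expect_true(any(pep$element == "H"))
  expect_equal(nrow(heavyAtoms(pep)$xyz), sum(pep$element != "H"))
  expect_false(any(grepl("\\|H$", heavyAtoms(pep)$key)))
})

test_that("structural validation errors are informative", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeFixturePdb(f)
  expect_error(suppressWarnings(readComplex(f, "Q", "B")),
               "available polymer chains: A, B")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeFixturePdb(f2, modifiedResidue = TRUE)
  expect_error(suppressWarnings(readComplex(f2, "A", "B")), "MSE")
  # peptide length outside the benchmark range warns but parses
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeFixturePdb(f3, nRec = 10, nPep = 7)
  expect_warning(cx <- readComplex(f3, "A", "B"), "outside the benchmark")
  expect_equal(length(unique(peptideAtoms(cx)$resno)), 7L)
})

test_that("write/read round trip preserves coordinates and numbering", {
  pep <- makePeptide("ADKLFGAYSE", "helix")
  tc <- makeToyComplex(12, peptide = pep, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeComplex(tc$complex, f)
  back <- suppressWarnings(readComplex(f, "A", "B"))
  expect_equal(coordsOf(receptorAtoms(back)), coordsOf(receptorAtoms(tc$complex)),
               tolerance = 1e-3)
  expect_equal(coordsOf(peptideAtoms(back)), coordsOf(peptideAtoms(tc$complex)),
               tolerance = 1e-3)
  expect_identical(peptideAtoms(back)$resno, peptideAtoms(tc$complex)$resno)
  expect_identical(peptideAtoms(back)$elety, peptideAtoms(tc$complex)$elety)
  # atom serials re-emitted sequentially
  serials <- as.integer(substr(grep("^ATOM", readLines(f), value = TRUE), 7, 11))
  expect_identical(serials, seq_along(serials))
  # insertion codes preserved
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeFixturePdb(f4, withInsert = TRUE)
  cxi <- suppressWarnings(readComplex(f4, "A", "B"))
  expect_true(any(nzchar(peptideAtoms(cxi)$insert)))
  f5 <- withr::local_tempfile(fileext = ".pdb")
  writeComplex(cxi, f5)
  back2 <- suppressWarnings(readComplex(f5, "A", "B"))
  expect_identical(peptideAtoms(back2)$insert, peptideAtoms(cxi)$insert)
})

test_that("multi-model files are read as ranked poses", {
  pep <- makePeptide("ADKLFGAYSE", "helix")
  tc <- makeToyComplex(12, peptide = pep, seed = 3)
  dk <- makeDecoys(tc$complex, list(
    decoySpec(), decoySpec(transform = RigidTransform(translation = c(3, 0, 0)))))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePoses(dk$models, f)
  poses <- readPoses(f, "A", "B")
  expect_length(poses, 2L)
  expect_equal(coordsOf(peptideAtoms(poses[[2]])),
               coordsOf(peptideAtoms(dk$models[[2]])), tolerance = 1e-3)
})

test_that("backbone and heavy-atom selections follow their definitions", {
  pep <- makePeptide("GDKLFGAYSE", "helix")   # starts with glycine
  bb <- backboneAtoms(pep)
  expect_equal(nrow(bb$xyz), 40L)             # 4 atoms per residue
  expect_identical(unique(sub(".*\\|", "", bb$key)), c("N", "CA", "C", "O"))
  expect_equal(nrow(backboneAtoms(pep, convention = "NCAC")$xyz), 30L)
  # residue missing O contributes 3 atoms
  drop <- pep[!(pep$resno == 4 & pep$elety == "O"), ]
  expect_equal(nrow(backboneAtoms(drop)$xyz), 39L)
  # glycine has 4 heavy atoms, alanine-like residues 5
  hv <- heavyAtoms(pep)
  perRes <- table(hv$resKey)
  expect_equal(unname(perRes[["1:GLY"]]), 4L)
  expect_equal(unname(perRes[["2:ASP"]]), 5L)  # CB-level side chains
  # heavy count equals an independent element scan
  expect_equal(nrow(hv$xyz), sum(!(toupper(pep$element) %in% c("H", "D"))))
})

test_that("cleaning is idempotent", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeFixturePdb(f, withWater = TRUE, withIon = TRUE, withAltloc = TRUE)
  cx <- suppressWarnings(readComplex(f, "A", "B"))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeComplex(cx, f2)
  cx2 <- suppressWarnings(readComplex(f2, "A", "B"))
  expect_equal(coordsOf(receptorAtoms(cx2)), coordsOf(receptorAtoms(cx)),
               tolerance = 1e-3)
  expect_identical(nrow(receptorAtoms(cx2)), nrow(receptorAtoms(cx)))
})
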