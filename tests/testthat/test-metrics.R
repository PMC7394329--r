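test_that("contact definition is inclusive at the 5 A boundary", {
  mk <- function(dx) {
    rec <- atomRows(at("CA", "GLY", 1, c(0, 0, 0)))
    pep <- atomRows(at("CA", "GLY", 1, c(dx, 0, 0), chain = "B"))
    PeptideComplex("b", rec, pep)
  }
  expect_equal(length(residueContacts(mk(4.99))), 1L)
  expect_equal(length(residueContacts(mk(5.00))), 1L)
  expect_equal(length(residueContacts(mk(5.01))), 0L)
  expect_equal(length(residueContacts(mk(100))), 0L)
})

test_that("residue contacts equal the brute-force enumeration", {
  for (s in c(2, 5, 8, 12)) {
    tc <- makeToyComplex(20, seed = s)
    expect_identical(contactKeys(tc$contacts),
                     bruteContactPairs(tc$complex))
    # binding site is the receptor-side projection of the contact set
    expect_identical(sort(bindingSiteResidues(tc$complex)),
                     sort(unique(contactPairs(tc$contacts)$receptor)))
  }
  # far-away peptide: no binding site, with a warning
  tc <- makeToyComplex(15, seed = 2)
  far <- makeDecoys(tc$complex, list(
    decoySpec(transform = RigidTransform(translation = c(100, 0, 0)))))
  expect_warning(bs <- bindingSiteResidues(far$models[[1]]), "no receptor")
  expect_length(bs, 0L)
})

test_that("FNAT follows its fraction definition", {
  tc <- makeToyComplex(24, seed = 6)
  native <- tc$complex
  expect_equal(computeFnat(native, native), 1.0)
  far <- makeDecoys(native, list(
    decoySpec(transform = RigidTransform(translation = c(100, 0, 0)))))
  expect_equal(computeFnat(native, far$models[[1]]), 0.0)
  # partially preserved contacts: FNAT equals the hand intersection
  near <- makeDecoys(native, list(
    decoySpec(transform = RigidTransform(translation = c(1.5, 0.8, 0)))))
  model <- near$models[[1]]
  natKeys <- bruteContactPairs(native)
  modKeys <- bruteContactPairs(model)
  expect_equal(computeFnat(native, model),
               length(intersect(natKeys, modKeys)) / length(natKeys))
  # no native contacts is an error, not FNAT = 0
  expect_error(computeFnat(far$models[[1]], far$models[[1]]),
               "no native contacts")
})

test_that("L-RMSD equals pure translations exactly and is receptor-framed", {
  tc <- makeToyComplex(20, seed = 9)
  native <- tc$complex
  expect_equal(computeLrmsd(native, native), 0)
  # peptide translated, receptor untouched: L-RMSD is the shift length
  for (t in c(0.5, 4, 20)) {
    dk <- makeDecoys(native, list(
      decoySpec(transform = RigidTransform(translation = c(0, t, 0)))))
    expect_lt(abs(computeLrmsd(native, dk$models[[1]]) - t), 1e-9)
  }
  # whole complex under a global rigid motion: all metrics unchanged
  tr <- randomTransform(13, translationSd = 30)
  moved <- PeptideComplex(
    pdbId(native),
    receptor = transformAtoms(receptorAtoms(native), tr),
    peptide = transformAtoms(peptideAtoms(native), tr))
  expect_lt(computeLrmsd(native, moved), 1e-6)
  expect_lt(computeIrmsd(native, moved), 1e-6)
  expect_equal(computeFnat(native, moved), 1.0)
})

test_that("L-RMSD and I-RMSD agree with rotation-sampling oracles", {
  set.seed(77)
  tc <- makeToyComplex(14, seed = 4)
  native <- tc$complex
  dk <- makeDecoys(native, list(
    decoySpec(transform = randomTransform(31, translationSd = 3),
              dihedralNoise = 4, seed = 31)))
  model <- dk$models[[1]]
  expect_lt(abs(computeLrmsd(native, model) - oracleLrmsd(native, model)),
            1e-3)
  expect_lt(abs(computeIrmsd(native, model) - oracleIrmsd(native, model)),
            1e-3)
  # interface displaced along one axis, receptor fixed
  pep <- peptideAtoms(native); pep$y <- pep$y + 2
  shifted <- PeptideComplex(pdbId(native), receptorAtoms(native), pep)
  expect_lt(abs(computeIrmsd(native, shifted) -
                  oracleIrmsd(native, shifted)), 1e-3)
})

test_that("B-RMSD is a position-independent conformation comparison", {
  pep <- makePeptide("ADKLFGAYSE", "helix", lengthSd = 0.01, angleSd = 1,
                     seed = 3)
  tr <- randomTransform(8, translationSd = 40)
  moved <- transformAtoms(pep, tr)
  expect_lt(computeBrmsd(pep, moved), 1e-8)
  # one psi dihedral rotated by 5 degrees: equals an independent Kabsch
  # on the perturbed coordinates
  ic <- toInternal(pep)
  tb <- icTable(ic)
  row <- which(tb$elety == "N")[6]   # psi of residue 5
  tb$dihedral[row] <- tb$dihedral[row] + 5
  bent <- rebuildPeptide(new("InternalCoordinates", table = tb), "measured")
  got <- computeBrmsd(pep, bent)
  orc <- oracleSuperpose(backboneAtoms(bent)$xyz, backboneAtoms(pep)$xyz)
  expect_lt(abs(got - orc$rmsd), 1e-3)
  expect_gt(got, 0.01)
  expect_error(computeBrmsd(pep, makePeptide("ADKL", "helix")),
               "residue count")
})

test_that("evaluatePose bundles the three metrics and labels failures", {
  tc <- makeToyComplex(18, seed = 10)
  native <- tc$complex
  ev <- evaluatePose(native, native, rank = 2L, method = "toy")
  expect_equal(fnat(ev), 1.0)
  expect_equal(lRmsd(ev), 0)
  expect_equal(iRmsd(ev), 0)
  expect_equal(ev@rank, 2L)
  dk <- makeDecoys(native, list(
    decoySpec(transform = RigidTransform(translation = c(2, 1, 0)))))
  ev2 <- evaluatePose(native, dk$models[[1]])
  expect_equal(fnat(ev2), computeFnat(native, dk$models[[1]]))
  expect_equal(lRmsd(ev2), computeLrmsd(native, dk$models[[1]]))
  expect_equal(iRmsd(ev2), computeIrmsd(native, dk$models[[1]]))
  # mismatched residues fail with the metric named
  trunc <- PeptideComplex(pdbId(native), receptorAtoms(native),
                          peptideAtoms(native)[-(1:5), ])
  expect_error(evaluatePose(native, trunc), "FNAT")
})

test_that("FNAT decreases monotonically as the peptide is pulled away", {
  tc <- makeToyComplex(24, seed = 6)
  native <- tc$complex
  u <- c(0.3, 0.9, 0.2); u <- u / sqrt(sum(u^2))
  vals <- vapply(c(0, 1, 2.5, 4, 8, 50), function(d) {
    dk <- makeDecoys(native, list(
      decoySpec(transform = RigidTransform(translation = d * u))))
    computeFnat(native, dk$models[[1]])
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_equal(vals[1], 1.0)
  expect_equal(vals[length(vals)], 0.0)
})
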