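# A small hand-written pose table used across several blocks.
handTable <- function() {
  rows <- list()
  add <- function(id, method, rank, fnat, l, i)
    rows[[length(rows) + 1]] <<- data.frame(
      pdb_id = id, method = method, rank = rank, fnat = fnat,
      l_rmsd = l, i_rmsd = i, stringsAsFactors = FALSE)
  # method M1, complex C1: L-RMSDs (9, 4, 7) by rank
  add("C1", "M1", 1, 0.50, 9, 8); add("C1", "M1", 2, 0.80, 4, 3.5)
  add("C1", "M1", 3, 0.60, 7, 6)
  # method M1, complex C2: rank 1 already best
  add("C2", "M1", 1, 0.90, 1.2, 1.0); add("C2", "M1", 2, 0.40, 11, 10)
  add("C2", "M1", 3, 0.30, 14, 13)
  # method M2
  add("C1", "M2", 1, 0.20, 18, 17); add("C1", "M2", 2, 0.95, 0.8, 0.7)
  add("C1", "M2", 3, 0.10, 25, 24)
  add("C2", "M2", 1, 0.55, 6, 5.5); add("C2", "M2", 2, 0.65, 3, 2.8)
  add("C2", "M2", 3, 0.35, 9, 8.5)
  poseTable(do.call(rbind, rows))
}

test_that("pose tables are validated", {
  tb <- handTable()
  expect_s3_class(tb, "data.frame")
  bad <- tb; bad$rank[1] <- 5L
  expect_error(poseTable(bad), "non-contiguous")
  bad2 <- tb; bad2$fnat[2] <- 1.4
  expect_error(poseTable(bad2), "fraction")
  expect_error(poseTable(tb[, -3]), "lacks columns")
  big <- do.call(rbind, lapply(1:25, function(r) {
    x <- tb[1, ]; x$rank <- r; x
  }))
  expect_error(poseTable(big, poseBudget = 20L), "pose budget")
})

test_that("best pose is the argmin of L-RMSD within top-N", {
  tb <- handTable()
  # top pose: rank 1 by definition
  expect_equal(bestPose(tb, "C1", "M1", topN = 1)$rank, 1L)
  expect_equal(bestPose(tb, "C1", "M1", topN = 1)$l_rmsd, 9)
  # L-RMSDs (9, 4, 7): rank 2 wins at top-3
  expect_equal(bestPose(tb, "C1", "M1", topN = 3)$rank, 2L)
  # brute-force argmin on a larger synthetic group
  set.seed(5)
  big <- poseTable(data.frame(
    pdb_id = "X", method = "m", rank = 1:20,
    fnat = runif(20), l_rmsd = runif(20, 0, 30),
    i_rmsd = runif(20, 0, 30)))
  for (n in c(1, 3, 5, 10, 20)) {
    sub <- big[big$rank <= n, ]
    expect_equal(bestPose(big, "X", "m", n)$l_rmsd, min(sub$l_rmsd))
  }
})

test_that("summaries equal hand-computed averages and success rates", {
  tb <- handTable()
  s1 <- summarizePoses(tb, "M1", topN = 3, successCutoff = 2.0)
  # best poses: C1 -> (0.80, 4, 3.5), C2 -> (0.90, 1.2, 1.0)
  expect_equal(s1$mean_fnat_pct, 100 * mean(c(0.80, 0.90)))
  expect_equal(s1$mean_l_rmsd, mean(c(4, 1.2)))
  expect_equal(s1$mean_i_rmsd, mean(c(3.5, 1.0)))
  expect_equal(s1$success_pct, 50)          # only C2 under 2.0 A
  # success at a 4 A cutoff counts both
  expect_equal(successRate(tb, "M1", 3, 4.0), 100)
  expect_equal(successRate(tb, "M1", 1, 2.0), 50)
  expect_equal(successRate(tb, "M2", 1, 2.0), 0)
  # top-N monotonicity of the best-pose mean
  expect_lte(summarizePoses(tb, "M1", 3)$mean_l_rmsd,
             summarizePoses(tb, "M1", 1)$mean_l_rmsd)
  # fewer poses than requested: warns and uses what is there
  expect_warning(s5 <- summarizePoses(tb, "M1", topN = 5), "fewer than")
  expect_equal(s5$mean_l_rmsd, summarizePoses(tb, "M1", 3)$mean_l_rmsd)
})

test_that("success curves are non-decreasing and match pointwise rates", {
  tb <- handTable()
  grid <- c(0.5, 1, 2, 5, 10, 20, 30)
  cv <- successCurve(tb, "M2", 3, grid)
  expect_true(all(diff(cv$success_pct) >= 0))
  for (k in seq_along(grid))
    expect_equal(cv$success_pct[k], successRate(tb, "M2", 3, grid[k]))
  # all-native table: flat 100 %
  allnat <- poseTable(data.frame(pdb_id = rep(c("A", "B"), each = 2),
                                 method = "m", rank = c(1:2, 1:2),
                                 fnat = 1, l_rmsd = 0, i_rmsd = 0))
  expect_true(all(successCurve(allnat, "m", 2, grid)$success_pct == 100))
})

test_that("top-vs-best bins follow the documented boundaries", {
  # differences (0, 0.5, 3.0, 12.0): one complex in each of four bins
  mk <- function(id, topL, bestL) data.frame(
    pdb_id = id, method = "m", rank = 1:2, fnat = 0.5,
    l_rmsd = c(topL, bestL), i_rmsd = c(topL, bestL))
  tb <- poseTable(rbind(mk("a", 5, 5), mk("b", 5.5, 5), mk("c", 8, 5),
                        mk("d", 17, 5)))
  bins <- bestMinusTopBins(tb, "m")
  expect_equal(bins$pct[bins$bin == "0.00"], 25)
  expect_equal(bins$pct[bins$bin == "0.00-1.00"], 25)
  expect_equal(bins$pct[bins$bin == "1.00-2.00"], 0)
  expect_equal(bins$pct[bins$bin == "2.00-5.00"], 25)
  expect_equal(bins$pct[bins$bin == ">10.00"], 25)
  expect_equal(sum(bins$pct), 100, tolerance = 1e-10)
  # boundary values go to the left-exclusive/right-inclusive bin
  tb2 <- poseTable(rbind(mk("a", 6, 5), mk("b", 7, 5), mk("c", 10, 5),
                         mk("d", 15, 5)))
  bins2 <- bestMinusTopBins(tb2, "m")
  expect_equal(bins2$pct[bins2$bin == "0.00-1.00"], 25)  # diff exactly 1
  expect_equal(bins2$pct[bins2$bin == "1.00-2.00"], 25)  # diff exactly 2
  expect_equal(bins2$pct[bins2$bin == "2.00-5.00"], 25)  # diff exactly 5
  expect_equal(bins2$pct[bins2$bin == "5.00-10.00"], 25) # diff exactly 10
})

test_that("consensus pooling beats every individual method", {
  tb <- handTable()
  cons <- consensusBest(tb)
  # per complex: pooled minimum over both methods
  expect_equal(cons$perComplex$l_rmsd[cons$perComplex$pdb_id == "C1"], 0.8)
  expect_equal(cons$perComplex$l_rmsd[cons$perComplex$pdb_id == "C2"], 1.2)
  expect_equal(cons$mean_l_rmsd, mean(c(0.8, 1.2)))
  for (m in c("M1", "M2"))
    expect_lte(cons$mean_l_rmsd, summarizePoses(tb, m, 3)$mean_l_rmsd)
  # single method: consensus equals that method's best poses
  solo <- tb[tb$method == "M1", ]
  expect_equal(consensusBest(solo)$mean_l_rmsd,
               summarizePoses(solo, "M1", 3)$mean_l_rmsd)
  # best-by-FNAT alternative
  consF <- consensusBest(tb, by = "fnat")
  expect_equal(consF$perComplex$fnat[consF$perComplex$pdb_id == "C1"], 0.95)
})

test_that("reproducibility differences are first-minus-second and antisymmetric", {
  tb <- handTable()
  expect_equal(unlist(reproducibilityDiff(tb, tb, "M1", 3)[, 3:5],
                      use.names = FALSE), c(0, 0, 0))
  second <- tb
  second$l_rmsd[second$pdb_id == "C1" & second$method == "M1" &
                  second$rank == 2] <- 5
  d12 <- reproducibilityDiff(tb, second, "M1", 3)
  expect_equal(d12$d_l_rmsd, mean(c(4, 1.2)) - mean(c(5, 1.2)))
  d21 <- reproducibilityDiff(second, tb, "M1", 3)
  expect_equal(d12$d_l_rmsd, -d21$d_l_rmsd)
  expect_error(reproducibilityDiff(tb, tb[tb$pdb_id == "C1", ], "M1", 3),
               "different complexes")
})

test_that("resolution bins split the shipped benchmark set correctly", {
  expect_equal(classifyResolution(1.55), "1-2")
  expect_equal(classifyResolution(2.40), "2-3")
  expect_equal(classifyResolution(2.00), "2-3")
  expect_error(classifyResolution(7), "plausible")
  meta <- read.delim(system.file("extdata", "benchmark_complexes.tsv",
                                 package = "PepDockBench"))
  expect_equal(nrow(meta), 133L)
  # brute recount against the classifier: strictly below 2.0 vs the rest
  bins <- classifyResolution(meta$resolution)
  expect_equal(unname(table(bins)["1-2"]), sum(meta$resolution < 2))
  expect_equal(unname(table(bins)["1-2"]), 90L)
  expect_equal(unname(table(bins)["2-3"]), 43L)
  expect_true(all(meta$peptide_length >= 9 & meta$peptide_length <= 15))
})

test_that("rotatable-bond counting follows the documented graph rule", {
  # poly-glycine: interior residues contribute N-CA and CA-C; terminal
  # N-CA is excluded (univalent N), both terminal CA-C bonds count
  expect_equal(countRotatableBonds(rep("GLY", 9)), 7 * 2 + 3)
  # alanine dipeptide by hand: CA1-C1, N2-CA2, CA2-C2
  expect_equal(countRotatableBonds(c("ALA", "ALA")), 3)
  # additivity: every added interior residue contributes a fixed number
  perResidue <- function(rn) {
    countRotatableBonds(c("GLY", rep(rn, 2), "GLY")) -
      countRotatableBonds(c("GLY", rn, "GLY"))
  }
  expect_equal(perResidue("LYS"), 2 + 4)   # backbone 2 + side chain 4
  expect_equal(perResidue("PHE"), 2 + 2)   # ring bonds frozen
  expect_equal(perResidue("PRO"), 1)       # ring freezes N-CA too
  expect_equal(perResidue("ALA"), 2)
  expect_error(countRotatableBonds("XYZ"), "unknown residue")
  # classification boundaries
  expect_equal(classifyRotatableBonds(c(40, 41, 60, 61)),
               c("0-40", "41-60", "41-60", ">60"))
  expect_error(classifyRotatableBonds(-1), "negative")
})

test_that("secondary-structure classes use the 60 percent rule", {
  expect_equal(classifySecondaryStructure("HHHHHHHHHH"), "regular")
  expect_equal(classifySecondaryStructure("CCCCCCCCCC"), "coil")
  expect_equal(classifySecondaryStructure("HHHHHHCCCC"), "regular") # 60 %
  expect_equal(classifySecondaryStructure("HHHHHCCCCC"), "coil")    # 50 %
  expect_equal(classifySecondaryStructure("GGEEBTTSCC"), "coil")    # 50 %
  expect_equal(classifySecondaryStructure("GGGEEBITTC"), "regular") # 70 %
  expect_error(classifySecondaryStructure("HHH", peptideLength = 10),
               "length")
})

test_that("group summaries partition and reweight to the global mean", {
  tb <- handTable()
  labels <- data.frame(pdb_id = c("C1", "C2"), group = c("g1", "g2"))
  gs <- groupSummary(tb, labels, methods = "M1", topN = 3L)
  expect_equal(nrow(gs), 2L)
  glob <- summarizePoses(tb, "M1", 3)
  wmean <- sum(gs$mean_l_rmsd * gs$n_complexes) / sum(gs$n_complexes)
  expect_equal(wmean, glob$mean_l_rmsd)
  # one group holding everything equals the global summary
  all1 <- groupSummary(tb, data.frame(pdb_id = c("C1", "C2"),
                                      group = "all"),
                       methods = "M1", topN = 3L)
  expect_equal(all1$mean_fnat_pct, glob$mean_fnat_pct)
  expect_error(groupSummary(tb, labels[1, , drop = FALSE]), "unlabelled")
})
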