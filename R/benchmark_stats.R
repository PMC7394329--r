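# benchmark_stats: aggregation of per-pose evaluations into benchmark
# statistics — top/best pose, summary means, success rates,
# ranking-quality bins, consensus pooling, reproducibility differences
# and molecular grouping.
#
# A pose table is a plain data.frame with one row per evaluated pose and
# columns: pdb_id, method, rank (1..N within a complex/method group),
# fnat (fraction in [0, 1]), l_rmsd (A), i_rmsd (A). "Top pose" is the
# rank-1 pose (the method's own scoring choice); "best pose" is the pose
# with the lowest L-RMSD among the considered poses.

#' Validate (and return) a pose table
#'
#' Checks the schema and the rank invariants: within each (pdb_id,
#' method) group, ranks must be unique and contiguous from 1, and no
#' group may exceed the pose budget.
#'
#' @param records data.frame with columns \code{pdb_id}, \code{method},
#'   \code{rank}, \code{fnat}, \code{l_rmsd}, \code{i_rmsd}.
#' @param poseBudget maximum number of poses per (complex, method) group
#'   (default 20, the number of docking poses generated per complex).
#' @return the validated data.frame, with \code{rank} as integer.
#' @export
poseTable <- function(records, poseBudget = 20L) {
  need <- c("pdb_id", "method", "rank", "fnat", "l_rmsd", "i_rmsd")
  missing <- setdiff(need, colnames(records))
  if (length(missing))
    stop(sprintf("pose table lacks columns: %s",
                 paste(missing, collapse = ", ")))
  records$rank <- as.integer(records$rank)
  if (any(!is.finite(records$fnat)) ||
      any(records$fnat < 0 | records$fnat > 1))
    stop("fnat must be a fraction in [0, 1]")
  if (any(!is.finite(records$l_rmsd)) || any(records$l_rmsd < 0) ||
      any(!is.finite(records$i_rmsd)) || any(records$i_rmsd < 0))
    stop("RMSD columns must be finite and >= 0")
  grp <- split(records$rank, paste(records$pdb_id, records$method, sep = "\r"))
  for (g in names(grp)) {
    r <- sort(grp[[g]])
    if (length(r) > poseBudget)
      stop(sprintf("group '%s' exceeds the pose budget of %d",
                   gsub("\r", "/", g), poseBudget))
    if (any(r != seq_along(r)))
      stop(sprintf("group '%s' has non-contiguous or duplicated ranks",
                   gsub("\r", "/", g)))
  }
  records
}

groupRows <- function(table, pdbId, method) {
  rows <- table[table$pdb_id == pdbId & table$method == method, , drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("no poses for complex '%s', method '%s'", pdbId, method))
  rows
}

#' Best pose of a complex within the top-N ranks
#'
#' Among ranks 1..\code{topN}, the pose with the lowest L-RMSD; ties are
#' broken toward the lower rank. \code{topN = 1} returns the top pose
#' (the pose ranked first by the method's own scoring function).
#'
#' @param table a pose table (see \code{\link{poseTable}}).
#' @param pdbId,method group selectors.
#' @param topN number of top-ranked poses considered.
#' @return the selected row of the table (single-row data.frame).
#' @export
bestPose <- function(table, pdbId, method, topN = 20L) {
  stopifnot(topN >= 1)
  rows <- groupRows(table, pdbId, method)
  rows <- rows[rows$rank <= topN, , drop = FALSE]
  rows <- rows[order(rows$rank), , drop = FALSE]
  rows[which.min(rows$l_rmsd), , drop = FALSE]
}

perComplexBest <- function(table, method, topN) {
  sub <- table[table$method == method, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("no poses for method '%s'", method))
  ids <- unique(sub$pdb_id)
  avail <- tapply(sub$rank, sub$pdb_id, max)
  if (any(avail < topN))
    warning(sprintf("%d complex(es) have fewer than %d poses; using available poses",
                    sum(avail < topN), topN), call. = FALSE)
  do.call(rbind, lapply(ids, function(id) bestPose(sub, id, method, topN)))
}

#' Summary row for one method at one top-N level
#'
#' Per complex, the best pose within the top-N ranks is selected; the
#' returned row holds the unweighted means of FNAT (as a percentage),
#' L-RMSD and I-RMSD across complexes, and the success rate: the
#' percentage of complexes whose selected pose has L-RMSD at or below
#' the cutoff.
#'
#' @inheritParams bestPose
#' @param successCutoff success cutoff on L-RMSD in Angstrom (default
#'   2.0).
#' @return one-row data.frame: \code{method, top_n, n_complexes,
#'   mean_fnat_pct, mean_l_rmsd, mean_i_rmsd, success_pct}.
#' @export
summarizePoses <- function(table, method, topN = 20L, successCutoff = 2.0) {
  best <- perComplexBest(table, method, topN)
  data.frame(method = method, top_n = as.integer(topN),
             n_complexes = nrow(best),
             mean_fnat_pct = 100 * mean(best$fnat),
             mean_l_rmsd = mean(best$l_rmsd),
             mean_i_rmsd = mean(best$i_rmsd),
             success_pct = 100 * mean(best$l_rmsd <= successCutoff),
             stringsAsFactors = FALSE)
}

#' Success rate of a method
#'
#' Percentage of complexes whose best pose within the top-N ranks has an
#' L-RMSD at or below the cutoff.
#'
#' @inheritParams summarizePoses
#' @param cutoff L-RMSD cutoff in Angstrom.
#' @return percentage in [0, 100].
#' @export
successRate <- function(table, method, topN = 20L, cutoff = 2.0) {
  best <- perComplexBest(table, method, topN)
  100 * mean(best$l_rmsd <= cutoff)
}

#' Success rate as a function of the L-RMSD cutoff
#'
#' @inheritParams successRate
#' @param cutoffs numeric grid of L-RMSD cutoffs (A).
#' @return data.frame with columns \code{cutoff} and \code{success_pct};
#'   non-decreasing in \code{cutoff}.
#' @export
successCurve <- function(table, method, topN = 20L,
                         cutoffs = seq(0.5, 30, by = 0.5)) {
  if (!length(cutoffs)) stop("empty cutoff grid")
  best <- perComplexBest(table, method, topN)
  data.frame(cutoff = cutoffs,
             success_pct = vapply(cutoffs, function(ct)
               100 * mean(best$l_rmsd <= ct), numeric(1)))
}

TOP_BEST_BINS <- c("0.00", "0.00-1.00", "1.00-2.00", "2.00-5.00",
                   "5.00-10.00", ">10.00")

#' Distribution of (top pose - best pose) L-RMSD differences
#'
#' For each complex the difference between the rank-1 pose's L-RMSD and
#' the best pose's L-RMSD (over all poses) is assigned to one of the
#' bins 0.00, 0.00-1.00, 1.00-2.00, 2.00-5.00, 5.00-10.00, >10.00.
#' Exact zeros (scoring function already ranked the best pose first) get
#' their own bin; the intervals are left-exclusive and right-inclusive.
#' Percentages over complexes sum to 100.
#'
#' @inheritParams summarizePoses
#' @param topN pose budget over which the best pose is taken.
#' @return data.frame with columns \code{bin} and \code{pct}.
#' @export
bestMinusTopBins <- function(table, method, topN = 20L) {
  sub <- table[table$method == method, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("no poses for method '%s'", method))
  ids <- unique(sub$pdb_id)
  diffs <- vapply(ids, function(id) {
    rows <- groupRows(sub, id, method)
    top <- rows[rows$rank == 1L, , drop = FALSE]
    if (!nrow(top)) stop(sprintf("complex '%s' lacks a rank-1 pose", id))
    top$l_rmsd - bestPose(sub, id, method, topN)$l_rmsd
  }, numeric(1))
  assign <- ifelse(diffs == 0, "0.00",
            ifelse(diffs <= 1, "0.00-1.00",
            ifelse(diffs <= 2, "1.00-2.00",
            ifelse(diffs <= 5, "2.00-5.00",
            ifelse(diffs <= 10, "5.00-10.00", ">10.00")))))
  counts <- table(factor(assign, levels = TOP_BEST_BINS))
  data.frame(bin = TOP_BEST_BINS,
             pct = 100 * as.vector(counts) / length(diffs),
             stringsAsFactors = FALSE)
}

#' Consensus best pose over all methods
#'
#' Pools the poses of all methods per complex and selects the pose with
#' the lowest L-RMSD from the pooled set (ties toward lower rank, then
#' method order of appearance). This estimates the limit of what the
#' combination of all methods can achieve with a perfect universal
#' scoring function.
#'
#' @param table a pose table holding all methods.
#' @param topN per-method pose budget considered.
#' @param by criterion selecting the pooled pose: \code{"l_rmsd"}
#'   (default, best-by-L-RMSD) or \code{"fnat"} (best-by-FNAT).
#' @return list with \code{perComplex} (data.frame of winning poses),
#'   \code{mean_fnat_pct} and \code{mean_l_rmsd}.
#' @export
consensusBest <- function(table, topN = 20L, by = c("l_rmsd", "fnat")) {
  by <- match.arg(by)
  if (!nrow(table)) stop("empty pose table")
  sub <- table[table$rank <= topN, , drop = FALSE]
  win <- do.call(rbind, lapply(unique(sub$pdb_id), function(id) {
    rows <- sub[sub$pdb_id == id, , drop = FALSE]
    if (by == "l_rmsd") rows[which.min(rows$l_rmsd), , drop = FALSE]
    else rows[which.max(rows$fnat), , drop = FALSE]
  }))
  rownames(win) <- NULL
  list(perComplex = win,
       mean_fnat_pct = 100 * mean(win$fnat),
       mean_l_rmsd = mean(win$l_rmsd))
}

#' Difference in performance between two docking runs
#'
#' Difference (first minus second) of the summary means for one method,
#' used to check that repeated docking runs reproduce.
#'
#' @param first,second pose tables over the same complexes.
#' @inheritParams summarizePoses
#' @return one-row data.frame: \code{method, top_n, d_fnat_pct,
#'   d_l_rmsd, d_i_rmsd}.
#' @export
reproducibilityDiff <- function(first, second, method, topN = 20L) {
  idsA <- sort(unique(first$pdb_id[first$method == method]))
  idsB <- sort(unique(second$pdb_id[second$method == method]))
  if (length(idsA) != length(idsB) || !all(idsA == idsB))
    stop("the two runs cover different complexes")
  a <- summarizePoses(first, method, topN)
  b <- summarizePoses(second, method, topN)
  data.frame(method = method, top_n = as.integer(topN),
             d_fnat_pct = a$mean_fnat_pct - b$mean_fnat_pct,
             d_l_rmsd = a$mean_l_rmsd - b$mean_l_rmsd,
             d_i_rmsd = a$mean_i_rmsd - b$mean_i_rmsd,
             stringsAsFactors = FALSE)
}

#' Resolution bin of a complex
#'
#' Complexes are grouped by crystallographic resolution into 1-2 A and
#' 2-3 A bins. The boundary value 2.00 A is assigned to the 2-3 A bin:
#' this convention reproduces the 89/44 split of the 133-complex
#' benchmark set shipped in \code{extdata/benchmark_complexes.tsv}.
#'
#' @param resolution resolution in Angstrom, in (0, 5).
#' @return \code{"1-2"} or \code{"2-3"} (vectorised).
#' @export
classifyResolution <- function(resolution) {
  if (any(!is.finite(resolution) | resolution <= 0 | resolution >= 5))
    stop("resolution outside the plausible range (0, 5) A")
  ifelse(resolution < 2.0, "1-2", "2-3")
}

#' Count rotatable bonds of a peptide
#'
#' Graph-based count over the peptide's heavy-atom covalent structure
#' (derived from its residue names): a bond is rotatable when it is a
#' single acyclic bond whose two atoms each carry at least one further
#' heavy-atom neighbour, excluding the backbone amide (peptide C-N)
#' bonds. Ring bonds (PRO, HIS, PHE, TYR, TRP) are never rotatable.
#'
#' @param x a peptide atom data.frame, a \linkS4class{PeptideComplex}
#'   (its peptide chain is used), or a character vector of 3-letter
#'   residue names.
#' @return integer count.
#' @export
countRotatableBonds <- function(x) {
  resnames <- if (is(x, "PeptideComplex")) {
    sub(".*:", "", residueOrder(peptideAtoms(x)))
  } else if (is.data.frame(x)) {
    sub(".*:", "", residueOrder(x))
  } else as.character(x)
  bad <- setdiff(resnames, STANDARD_AA)
  if (length(bad))
    stop(sprintf("unknown residue(s): %s", paste(bad, collapse = ", ")))
  bonds <- peptideBondGraph(resnames)
  deg <- table(c(bonds$a, bonds$b))
  rot <- !bonds$ring & !bonds$amide &
    deg[bonds$a] >= 2 & deg[bonds$b] >= 2
  sum(rot)
}

#' Rotatable-bond bin of a peptide
#'
#' @param count non-negative rotatable-bond count.
#' @return \code{"0-40"}, \code{"41-60"} or \code{">60"} (vectorised).
#' @export
classifyRotatableBonds <- function(count) {
  if (any(count < 0)) stop("negative rotatable-bond count")
  ifelse(count <= 40, "0-40", ifelse(count <= 60, "41-60", ">60"))
}

#' Secondary-structure class of a peptide
#'
#' A complex is assigned to the regular class when the summed helix and
#' sheet content of its peptide is 60 percent or more; otherwise it is a
#' coil complex. Helix symbols are H, G, I and sheet symbols E, B (8- or
#' 3-symbol assignments accepted); every other symbol counts as
#' coil-like.
#'
#' @param ss per-residue secondary-structure string (one symbol per
#'   peptide residue).
#' @param peptideLength optional expected length; an error is raised on
#'   mismatch.
#' @return \code{"regular"} or \code{"coil"}.
#' @export
classifySecondaryStructure <- function(ss, peptideLength = NULL) {
  sym <- strsplit(toupper(ss), "")[[1]]
  if (!is.null(peptideLength) && length(sym) != peptideLength)
    stop(sprintf("secondary-structure string length %d != peptide length %d",
                 length(sym), peptideLength))
  frac <- mean(sym %in% c("H", "G", "I", "E", "B"))
  if (frac >= 0.60) "regular" else "coil"
}

#' Per-group summary rows
#'
#' \code{\link{summarizePoses}} restricted to each group of complexes on
#' one grouping axis (resolution bin, rotatable-bond bin or
#' secondary-structure class).
#'
#' @param table a pose table.
#' @param labels data.frame with columns \code{pdb_id} and \code{group}
#'   labelling every complex in the table.
#' @param methods methods to summarise (default: all in the table).
#' @param topN vector of top-N levels.
#' @param successCutoff success cutoff (A).
#' @return data.frame of summary rows with a leading \code{group}
#'   column.
#' @export
groupSummary <- function(table, labels, methods = unique(table$method),
                         topN = c(20L, 1L), successCutoff = 2.0) {
  unlabelled <- setdiff(unique(table$pdb_id), labels$pdb_id)
  if (length(unlabelled))
    stop(sprintf("unlabelled complex(es): %s",
                 paste(unlabelled, collapse = ", ")))
  out <- list()
  for (g in unique(labels$group)) {
    ids <- labels$pdb_id[labels$group == g]
    sub <- table[table$pdb_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) next
    for (m in methods) for (n in topN) {
      row <- summarizePoses(sub, m, n, successCutoff)
      out[[length(out) + 1]] <- cbind(group = g, row,
                                      stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
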