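---
title: "Evaluating protein-peptide docking poses: methods and design"
author: "PepDockBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating protein-peptide docking poses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PepDockBench)
```

## The evaluation model

A docking benchmark compares a predicted protein-peptide complex with
the experimentally determined one. PepDockBench implements the three
CAPRI-style quality parameters as its core, on top of a strict
structure model: one receptor chain, one peptide chain, hetero-atoms
and waters removed, alternate locations reduced to the 'A' set, and
only the 20 standard amino acids admitted (a modified residue makes a
complex unusable as a reference and is an error, not a silent drop).
Hydrogens are kept on reading but excluded from every metric: crystal
structures mostly lack them, and a metric whose value depends on
whether a model happens to include hydrogens would not be comparable
across methods.

**Contacts and FNAT.** Two residues across the interface are in
contact when their minimum heavy-atom distance is at most the cutoff
(default 5 Å, inclusive at the boundary). FNAT is the fraction of the
native contact set recovered by the model. A native complex with no
contacts at the cutoff leaves FNAT undefined; this is raised as an
error because such a complex cannot serve as a benchmark reference at
all.

**L-RMSD.** The receptor backbones of native and model are superposed
by unweighted least squares and the resulting transform is carried
onto the model peptide; the peptide backbone RMSD is then taken
without re-fitting. The quantity is therefore invariant under any
global rigid motion of the model, and for a decoy that only translates
the peptide by a vector *t* it equals |*t*| exactly — both properties
are enforced in the test suite at 1e-6 and 1e-9 Å respectively.

**I-RMSD.** Interface residues are defined on the native complex only
(any residue appearing in a native contact pair, both sides, at the
same 5 Å cutoff used for FNAT). The default fit frame is the interface
itself: the paired interface backbone atoms are superposed and the
post-fit RMSD returned. Whether the fit frame should be the interface
or the whole receptor is a genuinely open convention; both are
implemented (`fitFrame = "interface"` or `"receptor"`) and the
interface frame is the default because it isolates interface geometry
from receptor-wide deviations.

**Backbone convention.** "Backbone" means {N, CA, C, O} by default.
Including the carbonyl oxygen makes the conformation comparison
(B-RMSD) sensitive to peptide-plane flips that {N, CA, C} misses; the
three-atom convention is available via `convention = "NCAC"` for
compatibility with tools that exclude O.

**Residue pairing.** Native and model residues are paired strictly by
residue number + insertion code + residue name. A mismatch is an
error: silently intersecting two different sequences produces metric
values that look valid and are not. Within a matched residue, missing
atoms are skipped and the pairing keys keep both selections aligned.

## De-biasing peptide coordinates for blind docking

When the peptide of a native complex is handed to a docking program
unchanged, its coordinates already encode the answer. The shift
procedure removes that information while provably preserving the
peptide's conformation:

1. every heavy atom is expressed in internal coordinates — bond length
   to a parent, bond angle to a grandparent, signed dihedral to a
   great-grandparent — over a parentage tree rooted at the first
   backbone nitrogen (side chains hang off CA; the chain-continuity
   check rejects C–N gaps above 2.5 Å as chain breaks);
2. the peptide is rebuilt atom by atom in a canonical frame by
   natural-extension placement (first atom at the origin, second on
   +x, third in the xy-plane);
3. the rebuilt copy is rotated uniformly at random (quaternion
   sampling) and translated so that its centroid lies at least 50 Å
   from the receptor centroid and no heavy atom comes within 20 Å of
   any receptor atom.

Dihedrals are inputs to the rebuild, so they are preserved to
round-off regardless of the geometry mode. `"measured"` reuses the
stored bond lengths and angles, making the round trip exact up to
rigid motion (B-RMSD below 1e-6 Å). `"ideal"` substitutes standard
backbone geometry — N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C–O
1.231 Å, CA–CB 1.530 Å; angles N–CA–C 111.2°, CA–C–N 116.6°, C–N–CA
121.9°, CA–C–O 120.8°, N–CA–CB 110.5° — while keeping every dihedral.
This emulates rebuilding a peptide through a template-based toolchain
and produces the small, non-zero B-RMSD one expects from such a round
trip (typically 0.1–0.4 Å on jittered fixtures, always under 1 Å in
the test conditions); side-chain atoms beyond CB keep their measured
geometry because no single ideal value covers them.

The separation thresholds (50 Å centroid, 20 Å minimum atom distance)
are design choices, not physical constants: they guarantee zero
residue contacts at any reasonable cutoff (20 Å ≫ 5 Å) so the shifted
pose retains no binding-site information whatsoever. Both are
arguments of `shiftPeptide()`. Placement is seeded; the same seed
yields bit-identical coordinates.

## The synthetic benchmark generator

The generator exists so that every computation in the package can be
tested against ground truth known by construction, at the scale of the
study conditions the package targets: peptides of 9–15 residues
docked against single-chain receptors, 20 poses per complex and
method.

- `makePeptide()` builds peptides from canonical internal coordinates:
  helix φ/ψ = (−57°, −47°), strand (−119°, 113°), coil sampled per
  residue from two broad basins (α: φ ≈ −63 ± 10°, ψ ≈ −43 ± 10°; β:
  φ ≈ −120 ± 15°, ψ ≈ 130 ± 15°), all peptide bonds trans. Optional
  seeded jitter on bond lengths (0.015 Å) and angles (1.5°) emulates
  how crystal structures deviate from ideal covalent geometry — used
  wherever a test needs the "ideal" rebuild to be non-trivial.
- Side chains are built through CB only. The backbone carries every
  RMSD metric, and CB-level side chains already exercise heavy-atom
  contact logic; full rotamer libraries would add nothing the metrics
  can see.
- `makeToyComplex()` slides a peptide against a generated helical
  receptor until the minimum heavy-atom separation falls in the
  2.6–3.6 Å touching window, and returns the complex together with its
  exact contact set.
- `makeDecoys()` perturbs the native peptide (dihedral noise,
  coordinate noise, rigid transform — receptor fixed). For pure-rigid
  decoys the L-RMSD is known analytically from the transform acting on
  the backbone coordinates, giving the metrics module an exact oracle.

What the generator does **not** emulate: docking energetics and
scoring functions, clashes and packing at the interface beyond a
minimum-distance check, full side chains, solvent, crystallographic
artefacts (alternate conformations are exercised through hand-written
file fixtures instead). Passing tests therefore certify the
*evaluation machinery*, not any claim about how real docking methods
rank real complexes.

## Aggregation statistics and bin conventions

A pose table holds one row per (complex, method, rank) with FNAT
stored as a fraction and formatted as a percentage in reports. "Top
pose" is rank 1 — the method's own scoring choice; "best pose" is the
argmin of L-RMSD within the top-N, ties broken toward the lower rank
(a deterministic choice that favours the scoring function). Success is
L-RMSD ≤ cutoff, with 2.0 Å and 4.0 Å the conventional operating
points. Methods that produced fewer than the requested top-N poses are
averaged over what exists, with a warning — failing complexes are a
real feature of docking benchmarks and silently dropping them would
bias means.

Bin boundaries are fixed as follows, and exposed as code rather than
convention: the (top − best) L-RMSD difference bins treat exact zero
as its own category (the scoring function found the best pose) with
the remaining intervals left-exclusive/right-inclusive; rotatable-bond
groups are 0–40 / 41–60 / >60 on integer counts; resolution groups put
the boundary value 2.00 Å into the 2–3 Å bin, so the 1–2 Å class
contains only structures strictly better than 2 Å — under this rule
the shipped 133-complex metadata table splits 90/43. Secondary
structure uses helix = {H, G, I}, sheet = {E, B} over either 8- or
3-symbol assignments, with "regular" at 60 % or more combined content
(boundary inclusive); the assignment string itself is an input, since
assigning secondary structure is a solved problem with established
tools and bundling a reimplementation would only create disagreement.

Rotatable bonds are counted on the peptide's covalent template graph
(derived from residue names): a bond counts when it is single,
acyclic, not a backbone amide, and both atoms carry at least one
further heavy neighbour. This is a documented graph rule, not an
attempt at parity with any particular cheminformatics package —
group thresholds accept externally computed counts just as well.

Consensus pooling selects, per complex, the best pose across all
methods. The pooled mean FNAT is computed on the best-by-L-RMSD pose
by default; whether one should instead pool best-by-FNAT is ambiguous,
so both are exposed (`by = "l_rmsd"` / `by = "fnat"`).

## Numerical choices

- Superposition is SVD-based Kabsch with an explicit determinant
  correction forcing a proper rotation; degenerate (collinear) point
  sets are an error rather than an arbitrary answer. No outlier
  rejection, no weighting: every paired atom is fitted once.
- Torsions use the signed four-point atan2 form (IUPAC sign); the test
  suite cross-checks against an independent implementation.
- Contact cutoffs compare squared distances clamped at zero to avoid
  negative round-off under the outer-product expansion.
- All seeded functionality goes through a private RNG scope that
  restores the caller's random state, so library calls never perturb a
  user's simulation.

## Problem sizes and verification scale

The test suite and the acceptance script run the full pipeline at
deliberately modest sizes — toy complexes of 14–24 receptor residues
with 10-residue peptides, pools of 50 fixtures for the contact oracle,
12 complexes × 3 simulated methods × 20 poses for the aggregation
checks, 100 random rigid motions for the invariance property, 20
peptides for the shift contract. These sizes were chosen so that the
independent oracles (O(n²) contact enumeration, rotation-sampling
superposition with Nelder–Mead refinement) remain exact or
near-exact references; every property they certify is
size-independent by construction.

## Known limitations

- Only PDB-format input; one receptor chain and one peptide chain per
  complex (multi-chain receptors are out of scope by design).
- Missing atoms are skipped, never modelled; a reference complex with
  large gaps should be completed upstream.
- The ideal-geometry rebuild idealises backbone and CB only.
- No CAPRI star classification or composite quality scores: the
  package reports the primitive metrics and lets the user bin them.
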