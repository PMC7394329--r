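Package: PepDockBench
Title: Evaluation of Protein-Peptide Docking Poses with CAPRI Quality Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking protein-peptide docking methods.
    Computes the CAPRI pose-quality parameters (fraction of native
    contacts, ligand RMSD, interface RMSD) between a native complex and
    docked models, de-biases peptide starting coordinates for blind
    docking by rebuilding the peptide from its internal coordinates in a
    new frame, and aggregates per-pose results into benchmark statistics:
    top/best pose summaries, success rates, ranking-quality bins,
    consensus pooling across methods, reproducibility differences, and
    grouping of complexes by crystallographic resolution, peptide
    rotatable-bond count and secondary-structure content. Includes a
    synthetic structure and decoy generator with analytically known
    ground truth, and a command-line interface with single, batch, shift
    and stats modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
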