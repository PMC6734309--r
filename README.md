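# xlambig

Ambiguity-aware use of chemical cross-linking (XL-MS) distance restraints in
the modeling of homo-oligomeric protein complexes.

Homo-oligomers are built from sequence-identical subunits, so a cross-link
identified between residue numbers (r<sub>i</sub>, r<sub>j</sub>) cannot be
assigned as intra- or inter-subunit from peptide evidence alone. `xlambig`
provides the full machinery to quantify and exploit this ambiguity for
homo-dimers:

* **Distances** — straight-line Euclidean (EUC) and solvent accessible
  surface distance (SASD) between lysine C&alpha; atoms. SASD places the
  structure on a voxel grid, marks protein-occupied space, anchors each
  endpoint to the nearest solvent voxel and measures the shortest
  through-solvent path (26-connected Dijkstra/A* in C++; a strict
  6-connected mode is available).
* **Classification** — non-redundant candidate enumeration (at least one
  endpoint in the first chain, self pairs as inter-only) and the four-way
  label *Intra / Inter / Ambiguous / Non-accessible* at a linker threshold
  (33 &Aring; default, the usual DSS/BS3 bound), with EUC-vs-SASD
  cross-tabulation and threshold sweeps.
* **Scoring** — the MNXL score

  MNXL(d) = N(d; &mu; = 18.62, &sigma;&sup2; = 35.94) if d &le; 33 &Aring;, else &minus;0.1

  summed over inter-subunit cross-links, shaped by four axes: inclusion
  (`ALL` / `ONLY_BEST` / `NON_INTRA`), symmetry gating (`SYMMETRY_MATCHED` /
  `SYMMETRY_DIFFERENCE`, 5 &Aring; cutoff), orientation (`ORIENTED` /
  `STRINGENT`) and ambiguity handling (`OBLIVIOUS` / `NORMAL`). Named
  presets cover the standard variants (`normal-oriented-non-intra`,
  `symmetry-difference`, ...).
* **Benchmarking** — synthetic exact-C2 toy dimers with buried and exposed
  lysines, simulated cross-link sets, rigid-body decoy ensembles with a
  guaranteed near-native share, coverage subsampling, C&alpha;-RMSD with
  chain-mapping minimization, and top-10 near-native precision across
  scoring configurations.

## Worked example

```r
library(xlambig)

ref <- recreateReference(makeToyDimer(seed = 1))   # exact C2 toy dimer
xls <- simulateCrosslinks(ref)                     # SASD-matched lysine pairs
table(xls$label)
#> AMBIGUOUS     INTER     INTRA
#>         4         2         4

cfgs <- list(non_intra = scoringPreset("normal-oriented-non-intra", "SASD"),
             oblivious = scoringPreset("oblivious-oriented", "SASD"))
bench <- runBenchmark(list(toy1 = makeToyDimer(seed = 1),
                           toy2 = makeToyDimer(seed = 2)),
                      cfgs, nModels = 100, seed = 7)
bench$summary
#>      config mean sem n
#> 1 non_intra   90  10 2
#> 2 oblivious   50  10 2
```

Ten simulated cross-links are recovered from the reference, four of them
genuinely ambiguous. Ranking 100 rigid-body decoys per structure by total
inter-subunit MNXL, the conservative ambiguity-aware variant (`NON_INTRA`:
score inter alternatives only when the intra alternative is non-accessible)
places near-native models in the top 10 far more reliably than scoring every
alternative obliviously — the central practical finding the package
operationalizes.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/xlambig classify --pdb ref.pdb --out assignments.tsv
Rscript inst/scripts/xlambig simulate --pdb ref.pdb --out xls.tsv
Rscript inst/scripts/xlambig benchmark --seed 7 --outdir report/
```

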