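# aggremelt

Aggregation thermodynamics of coarse-grained peptide ensembles.

Short peptides in water either stay monomeric or associate into oligomers,
fibrils or gels. Replica-exchange simulations of a handful of chains (here
eight) in a cubic periodic box, run across a temperature ladder, yield
equilibrium ensembles from which the association propensity can be read off:
the fraction of chains in the full octamer, f<sub>8</sub>(T), decays
sigmoidally with temperature, and its midpoint T<sub>8m</sub> relative to the
incubation temperature (310 K) predicts whether the peptide aggregates.
`aggremelt` is the analysis side of that workflow, for structural
bioinformaticians working with multi-chain Cα-trace ensembles.

What it computes:

- **Sequence descriptors** — GRAVY (mean Kyte–Doolittle hydropathy), net
  charge at a given pH (Henderson–Hasselbalch over an injectable pKa set),
  and the cubic box side `(n / (C·N_A))^(1/3)` matching a molar
  concentration.
- **Oligomer identification** — two chains associate when any Cα–Cα
  distance is strictly below 7 Å under the minimum image convention;
  oligomers are the transitive closure (connected components) of that
  relation. Per frame, f<sub>m</sub> = m·count(m)/n.
- **Secondary structure from the Cα trace** — β/α/coil per residue from
  virtual-bond dihedrals plus a hydrogen-bond proxy on pseudo-peptide
  centers (β requires an inter- or intra-chain ladder of ≥ 2 rungs; lone
  extended chains are coil).
- **Binless WHAM** — free energies f<sub>k</sub> per ladder rung from
  `exp(-f_k) = Σ_i exp(-β_k E_i) / Σ_l N_l exp(f_l - β_l E_i)`, normalized
  snapshot weights w<sub>i</sub>(T) at any target temperature, ensemble
  averages `Σ_i w_i(T) v_i`, and C<sub>v</sub>(T) from energy fluctuations.
- **Melting statistics** — logistic-fit midpoints (T<sub>8m</sub>),
  inflection temperatures of the β fraction, heat-capacity peaks,
  the σ<sub>f8</sub> window-convergence diagnostic, and OLS regressions of
  melting temperature on descriptors.
- **Conformational clustering** — Ward's minimum-variance method on a
  permutation-aware multi-chain RMSD, WHAM-weighted cluster ranking, medoid
  representatives, per-residue RMSF.
- **A synthetic generator** — a replica-exchange Monte Carlo sampler over an
  exactly enumerable chain-partition Hamiltonian
  (`E(P) = -ε·Σ_b C(|b|,2)`, entropic factor `ν^|P|`), rendered into Cα
  coordinates, so the whole pipeline is testable against closed-form
  thermodynamics.

## Worked example

Descriptors for the bundled 20-peptide study table:

```r
library(aggremelt)
tab <- readPeptideTable(system.file("extdata", "peptides.tsv",
                                    package = "aggremelt"))
d <- descriptorTable(tab, pH = 7, nChains = 8)
head(d[, c("name", "sequence", "n", "gravy3", "charge1", "box_side1")], 4)
#>   name sequence n gravy3 charge1 box_side1
#>  CysZ1   ARKQIV 6 -0.233       3     146.7
#>  CysZ2   RKQIVA 6 -0.233       3     146.7
#>  CysZ3   KQIVAG 6  0.450       2     139.6
#>  CysZ4   QIVAGV 6  1.800       1     173.0
```

GRAVY −0.233 marks CysZ1 as mildly hydrophilic; the 146.7 Å box side puts
8 chains at its experimental 4.210 mM concentration.

End-to-end melting analysis on a synthetic ensemble with an exactly known
midpoint:

```r
spec <- toyModelSpec(epsilon = 0.65, multiplex = 2L, nSweeps = 8000L,
                     seed = 7L)
ens <- sampleEnsemble(spec, renderCoords = FALSE)  # 24 trajectories, 12 temps
w   <- renderFrames(analysisWindow(ens, windowFrames = 512L, stride = 8L))
fm  <- oligomerFractionMatrix(w)                   # f_mi per frame
wt  <- solveWham(w)                                # binless WHAM
f8  <- ensembleAverage(wt, fm[, 8], grid = seq(260, 370, by = 1),
                       label = "f8")
midpointTemperature(f8)
#> [1] 310.94
oracleMidpoint(enumeratePartitionModel(spec))      # exact enumeration
#> [1] 311.267
```

The fitted octamer-dissociation midpoint (310.9 K) recovers the exact
partition-function midpoint (311.3 K) to within the Monte Carlo noise of the
1536 analysis snapshots.

## Package layout

- `R/descriptors.R` — GRAVY, net charge, box sizing, peptide-table I/O
- `R/ensemble.R` — ensemble containers, PDB/TSV/config I/O, windowing,
  minimum image
- `R/oligomers.R` — contact criterion and oligomer partitions
- `R/secstruct.R` — β/α/coil assignment and state fractions
- `R/wham.R` — binless WHAM, ensemble averages, heat capacity
- `R/melting.R` — midpoints, inflections, peaks, convergence, regression
- `R/cluster.R` — frame metric, Ward clustering, representatives, RMSF
- `R/toymodel.R` — partition-model enumeration, replica-exchange sampler,
  coordinate rendering, reference geometries
- `vignettes/aggregation-melting.Rmd` — the methods vignette
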