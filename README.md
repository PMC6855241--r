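# allopath

Allosteric communication analysis for receptor dimer ensembles.

G protein-coupled receptors form dimers, and a small molecule bound at the
protein–protein interface can remodel the orthosteric (drug-binding) pocket
of each protomer. `allopath` implements the analysis chain used to study
that kind of cross-talk from a conformational ensemble:

- **Protein structure networks (PSN).** Residues are nodes; for residues
  *i*, *j* the interaction percentage is

  *I*<sub>ij</sub> = 100 · *n*<sub>ij</sub> / √(*N*<sub>i</sub>·*N*<sub>j</sub>),

  where *n*<sub>ij</sub> counts side-chain heavy-atom pairs within a
  distance cutoff (default 4.5 Å) and *N*<sub>i</sub> are residue-type
  normalization factors. An edge forms when *I*<sub>ij</sub> ≥ *I*<sub>min</sub>.
- **Dynamic cross-correlation (DCC).**
  *C*<sub>ij</sub> = ⟨Δ**r**<sub>i</sub>·Δ**r**<sub>j</sub>⟩ /
  √(⟨|Δ**r**<sub>i</sub>|²⟩⟨|Δ**r**<sub>j</sub>|²⟩) ∈ [−1, 1] over Cα
  displacements, optionally after superposing frames onto the ensemble mean.
- **Communication pathways.** Minimum-hop Dijkstra searches on the PSN
  restricted to correlated edges (|*C*<sub>ij</sub>| ≥ corr_min), run per
  frame between every residue pair of two pockets; identical residue
  sequences are pooled and reported with their cross-frame frequency
  (headline count: distinct pathways recurring in ≥ 30 % of frames).
- **Conformational clustering.** Pairwise best-fit (Kabsch) RMSD over a
  selection, classical MDS embedding, k-means with seeded restarts, medoid
  representatives.
- **Interface geometry.** Protomer centroid distance, Shrake–Rupley SASA,
  buried-surface contact area, and POVME-style grid pocket volume.
- **MM-PBSA bookkeeping.** Per-frame combination
  *E*<sub>gas</sub> = *E*<sub>int</sub> + *E*<sub>ele</sub> + *E*<sub>vdw</sub>,
  *G*<sub>sol</sub> = *G*<sub>psolv</sub> + *G*<sub>npsolv</sub>
  (with *G*<sub>npsolv</sub> = γ·SASA, γ = 0.0072 kcal mol⁻¹ Å⁻²),
  *G* = *E*<sub>gas</sub> + *G*<sub>sol</sub>, binding energy
  ΔG = *G*<sub>complex</sub> − (*G*<sub>receptor</sub> + *G*<sub>ligand</sub>),
  and per-residue hot spots below −1 kcal/mol.
- **Screening enrichment.** ROC curves (TPR = TP/(TP+FN),
  FPR = FP/(FP+TN)) and trapezoidal AUC for active/decoy score tables;
  Lipinski rule-of-five checks.
- **Synthetic data with ground truth.** Gaussian-network-model ensembles
  with an analytic correlation matrix, two-chain ensembles with a planted
  communication pathway of known persistence, Gaussian active/decoy score
  sets with closed-form AUC — so every stage is testable without MD or
  docking engines.

## Worked example

```r
library(allopath)

# A dimer ensemble with a pathway planted between an interface pocket
# (chain A) and an orthosteric pocket (chain B), formed in 60 % of frames.
spec <- planted_path_spec(persistence = 0.6)
ens  <- make_planted_path_dimer(spec, n_frames = 100, seed = 7)

graphs <- psn_per_frame(ens, psn_config(i_min = 0))
tally  <- tally_paths(graphs, attr(ens, "source_pocket"),
                      attr(ens, "sink_pocket"))
tally
#> Communication pathways over 100 frame(s): 1 distinct, 1 at frequency >= 30%
#>                            path hops frequency
#> 1 A:1->A:5->A:8->B:4->B:7->B:12    5      0.58
```

The tally recovers the planted residue route exactly; its frequency (0.58)
is the realised fraction of frames in which the contacts along the route
were formed, and it clears the 30 % reporting threshold.

```r
# MM-PBSA bookkeeping on a component row (kcal/mol)
delta <- data.frame(E_vdw = -46.18, E_ele = -3.28, E_int = 0,
                    G_psolv = 7.07, G_npsolv = -4.38)
binding_energy(combine_components(delta))$dG
#> [1] -46.77

# Screening enrichment on a synthetic active/decoy set (effect size d = 1)
s <- make_screening_scores(40, 1440, d = 1, seed = 7)
auc(roc_points(s))
#> [1] 0.7004514
```

ΔG is the exact row-wise sum of the component identities; the AUC sits near
its closed-form expectation Φ(1/√2) ≈ 0.760 for this effect size (single
40-active replicates scatter around it).

End-to-end runs are driven by a config (R list or YAML) through
`run_pipeline()`; every effective parameter is echoed into the JSON report.

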