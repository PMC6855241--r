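---
title: "Methods: networks, pathways and energy bookkeeping in allopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: networks, pathways and energy bookkeeping in allopath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

`allopath` studies how a ligand bound at the protein–protein interface of a
receptor dimer communicates with the orthosteric pockets of the two
protomers. This vignette records the models the package implements, the
parameters that matter, and the design choices made where the methodology
is genuinely open.

## The structure-network model

A protein structure network (PSN) has one node per residue. For residues
$i$ and $j$, $n_{ij}$ counts side-chain atom pairs within a distance cutoff
(4.5 Å by default, the conventional PSN value; heavy atoms only unless
configured otherwise, glycine contributing through its C$\alpha$), and the
interaction percentage is

$$I_{ij} = 100\,\frac{n_{ij}}{\sqrt{N_i N_j}},$$

with $N_i$ a residue-type normalization factor. An edge joins $i$ and $j$
when $I_{ij} \ge I_{\min}$ and at least one atom pair is in contact.
Two normalization decisions deserve comment:

* **Square root vs. product.** The PSN literature normalises by
  $\sqrt{N_i N_j}$; a product form is occasionally seen. The square-root
  form is the default and `normalization_product = TRUE` selects the
  literal product.
* **The $N_i$ values.** No specific residue-type table is bundled. The
  default `"uniform"` mode sets $N_i = 100$ for every type, which makes
  $I_{ij}$ exactly the side-chain contact-pair count — transparent and free
  of invented constants. A user table (`"table"` mode) reweights by type
  when normalization factors from a larger simulation corpus are available.

Sequence-adjacent residues are excluded from edges by default: backbone
neighbours are trivially in contact and would otherwise provide
uninformative covalent shortcuts through every pathway. A flag restores
them. Non-protein residues (waters, ligands) are excluded from networks
unless explicitly ingested with `keep_hetatm = TRUE` and selected.

## Dynamic cross-correlation

Over an ensemble of frames, with $\Delta\mathbf r_i$ the displacement of
residue $i$'s C$\alpha$ from its ensemble mean,

$$C_{ij} = \frac{\langle \Delta\mathbf r_i \cdot \Delta\mathbf r_j\rangle}
{\sqrt{\langle|\Delta\mathbf r_i|^2\rangle\,\langle|\Delta\mathbf r_j|^2\rangle}}
\in [-1, 1],$$

where $+1$ is fully correlated and $-1$ fully anti-correlated motion.
Frames may first be superposed onto the iterated ensemble mean (two
refinement passes) to remove rigid-body motion; the superposition makes the
matrix invariant to per-frame global rotations up to the iteration's
convergence tolerance (order $10^{-3}$ in $C$). For ensembles generated in
a common reference frame — such as the package's own elastic-network
samples, which have no rigid-body component by construction — superposition
is unnecessary and `superpose = FALSE` compares directly against the
analytic correlations. Residues with zero displacement variance are
flagged, zeroed, and ignored by path filtering rather than propagating
0/0 artefacts.

## Communication pathways

The pathway search combines the two matrices: PSN edges whose endpoints are
insufficiently correlated ($|C_{ij}| < $ `corr_min`) are removed, and a
shortest path is sought between a source-pocket residue and a sink-pocket
residue by Dijkstra's algorithm with unit edge cost (minimum hop count).
The method text this package follows states only that the search "considers"
correlated motions; filtering *edges* by $|C_{ij}|$ was chosen because it
keeps the search a plain shortest-path problem and makes the threshold's
effect monotone (raising it can only remove routes). Tie rules make the
result deterministic: among equal-hop paths the largest summed $I_{ij}$
wins, then the lexicographically smallest residue sequence by
(chain, residue number).

Pathway *frequency* is defined per distinct residue sequence: the fraction
of frames whose filtered network yields that exact sequence as a shortest
source→sink path (counted once per frame even when several pocket pairs
produce it). This requires per-frame networks — frequencies cannot exist on
a single time-averaged network — and the headline count reports distinct
pathways with frequency ≥ 30 %, with the single highest-frequency pathway
alongside. Alternative tallies (per pocket-pair counts) can be derived from
the returned table, which keeps every distinct path and its frequency.

Defaults that are free parameters of the method, always echoed in pipeline
reports: $I_{\min} = 3$ %, `corr_min` $= 0.3$, `freq_min` $= 0.30$.

## Clustering and representatives

Conformations are compared by best-fit RMSD (Kabsch superposition with the
proper-rotation constraint, fitted on a stated selection such as interface
backbone atoms). k-means needs a vector space, so the RMSD matrix is
embedded by classical multidimensional scaling into at most
$\min(n_\mathrm{frames}-1, 10)$ dimensions before clustering; the best of
`n_init` seeded restarts by within-cluster sum of squares is kept. The
"centre" of a cluster is reported as its medoid — the member frame with the
smallest summed RMSD to the rest — because a representative must be an
actual conformation; a flag switches to the centroid-nearest frame. Ties go
to the lowest frame index. $k$ is a plain parameter (8 in the study design
this package mirrors); no automatic selection is attempted.

## Geometry

* **SASA** uses Shrake–Rupley with a deterministic golden-spiral quadrature
  (960 points/atom by default; isolated-sphere error well under 2 %),
  probe radius 1.4 Å, and Bondi-type van der Waals radii by element
  (overridable via a two-column table — the method description names no
  radius set, so the standard one is shipped and logged).
* **Contact area** between protomers is the buried-surface half-difference
  $(S_A + S_B - S_{AB})/2$, heavy atoms by default; tiny negative values
  from quadrature noise are floored at zero with a warning.
* **Pocket volume** is a POVME-style grid count inside an inclusion sphere
  (default spacing 0.5 Å; halving the spacing moves fixture pockets by
  under 3 %): a grid point contributes iff it lies outside every
  solvent-expanded atom sphere. The sphere centre defaults to the
  pocket-lining residue centroid.

## Energy bookkeeping

Per-frame MM-PBSA components combine exactly, row-wise:
$E_\mathrm{gas} = E_\mathrm{int} + E_\mathrm{ele} + E_\mathrm{vdw}$,
$G_\mathrm{sol} = G_\mathrm{psolv} + G_\mathrm{npsolv}$,
$G = E_\mathrm{gas} + G_\mathrm{sol}$, and
$\Delta G = G_\mathrm{complex} - (G_\mathrm{receptor} + G_\mathrm{ligand})$
under the single-trajectory convention (per-frame difference first, then
mean ± sd; a multi-trajectory flag differences the means and combines
spreads in quadrature). The conformational-entropy term is deliberately
omitted, as is standard when only relative binding strengths are of
interest, and the polar solvation term is always an input column — no
Poisson–Boltzmann solver is run here. The nonpolar term uses
$\gamma \cdot \mathrm{SASA}$ with $\gamma = 0.0072$ kcal mol$^{-1}$
Å$^{-2}$. The "±" on summaries is the $n-1$ standard deviation over frames
(the convention is not universal; it is stated here once and used
everywhere). Hot-spot residues are those with mean per-residue contribution
strictly below −1 kcal/mol; a residue at exactly the threshold is excluded.

## Screening evaluation

ROC curves rank ligands best-first under the docking-energy convention
(lower score = stronger; `higher_better` flips it) and emit one vertex per
distinct score, so ties advance TPR and FPR jointly; the trapezoidal AUC
then equals the Mann–Whitney probability of correctly ordering a random
active/decoy pair with half credit for ties, which is the property the test
suite asserts against an independent computation. Rule-of-five criteria are
inclusive (MW ≤ 500, logP ≤ 5, N/O acceptors ≤ 10, NH/OH donors ≤ 5); the
strict variant fails on any violation, the classic variant tolerates one.

## The synthetic-data module

The generators replace the study's MD and docking engines with models whose
ground truth is known in closed form:

* **Elastic-network ensembles** (`make_gnm_ensemble`). A helical
  C$\alpha$ trace (two offset, touching helices for a dimer) defines a
  Kirchhoff matrix at an 8 Å contact cutoff; frames are sampled from the
  zero-mean Gaussian with per-axis covariance `scale` × the Kirchhoff
  pseudo-inverse. The implied correlation matrix is attached, giving the
  cross-correlation stage an analytic oracle; sample estimates converge to
  it at the usual $1/\sqrt{n}$ rate (RMS ≈ 0.01 at 4,000–5,000 frames, the
  sizes used in the tests).
* **Planted-pathway dimers** (`make_planted_path_dimer`). Two 12-residue
  chains; each residue is a C$\alpha$ plus a three-atom side-chain branch.
  A designated residue route from an interface pocket (chain A) to an
  orthosteric pocket (chain B) has consecutive side-chain tips within the
  4.5 Å network cutoff in exactly the frames where a per-frame Bernoulli
  draw at the stated persistence is "on" (the whole route toggles together,
  so the route's tally frequency is the realised on-fraction — binomial
  around the persistence). Decoy contacts are persistent, restricted to
  residues outside the route and pockets, and the construction verifies on
  the union contact graph that the planted route is the unique minimum-hop
  source→sink path, retrying placement otherwise.
* **Score sets** (`make_screening_scores`) draw decoys from $N(0,1)$ and
  actives from $N(-d,1)$; the expected AUC is $\Phi(d/\sqrt2)$ and is
  attached as ground truth. The default class sizes, 40 actives and 1,440
  decoys (1:36), mirror the screening-library design of the study this
  package's workflow follows.
* **Energy tables** (`make_energy_table`) are independent Gaussian draws
  per component.

Every generator is a pure function of its specification and seed.

What passing against these generators shows — and does not. The ensembles
have exact topologies, isotropic Gaussian fluctuations, no solvent or
membrane, pseudo side chains without rotamers, and planted routes with
clean uniqueness; real trajectories have none of those simplifications.
Green tests therefore validate the *bookkeeping and algorithms* (counts,
thresholds, tie rules, estimators, convergence behaviour), not the physics
of any particular receptor system.

## Numerical choices and degenerate inputs

* PDB ingestion keeps the highest-occupancy alternate location (ties toward
  'A', then lexicographic) and errors on inconsistent MODEL topologies,
  naming the first offending atom; coordinates round-trip at the format's
  3-decimal precision. Residue identity is always (chain, author number,
  insertion code) — never positional indices.
* Superposition refuses fewer than three or collinear fit atoms; the
  reflection branch of the SVD is always corrected to a proper rotation.
* The Kirchhoff pseudo-inverse drops eigenvalues below $10^{-8}$ of the
  largest; more than one null mode means a disconnected contact graph and
  is reported as such (the fix is a larger cutoff).
* Zero-variance residues in DCC, empty clusters in k-means (restart, then
  error), single-class score tables (rejected at ROC time, accepted at
  ingestion), header-only tables, and empty pockets all raise early,
  specific errors rather than propagating NaN.
* Pipeline configs are YAML (or plain R lists); validation aggregates every
  problem into one message, each stage derives its stream from the single
  root seed, and reports contain no wall-clock content, so identical
  configs give byte-identical reports.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
make the statistical assertions sharp rather than to emulate production
trajectories: 4,000–5,000-frame elastic-network ensembles for correlation
recovery, 200-frame planted-path dimers for frequency recovery, 40-frame
ensembles for clustering, 500 random graphs (≤ 10 nodes) for the exhaustive
path oracle, and 1,000 replicate 1,480-ligand score tables for the
random-screening AUC limit. The headline numbers of the original
microsecond-scale membrane-MD study (pathway counts per protomer, per-snapshot
AUCs, trajectory geometry curves) depend on trajectories and docking runs
that are not redistributable, and are out of scope for the tests.

## Known limitations

* No mmCIF or binary trajectory formats; ensembles arrive as multi-model
  PDB.
* The PSN has no community/hub analysis and no energy-weighted variant.
* Pocket volume does not detect pockets; it measures a stated inclusion
  sphere.
* AUC confidence intervals and enrichment-factor variants are not
  implemented.
* The per-residue normalization table for $I_{ij}$ must be supplied by the
  user; the uniform default changes the absolute scale of $I_{ij}$ (and
  hence the meaning of $I_{\min}$) relative to published residue-type
  tables.
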