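---
title: "Comparing reduced and PTM-modified ensembles with ptmdyn: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing reduced and PTM-modified ensembles with ptmdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmdyn)
```

## The scientific setting

Glucose-6-phosphate dehydrogenase (G6PDH), the rate-limiting enzyme of the
oxidative pentose phosphate pathway, is allosterically activated in
cyanobacteria by the regulator protein OpcA. OpcA is redox-sensitive: its
cysteines can carry thiol post-translational modifications (PTMs) —
sulfenylation, S-nitrosylation, S-glutathionylation, or disulfide bonds —
and the modification state changes how OpcA binds and tunes the G6PDH
homotetramer. Near each G6PDH active site, two pairs of charged residues
(ASP33/ARG37 below, GLU241/ARG243 above) form a molecular *gate* whose
separation controls substrate access; the gate's conformational state
(closed, open, wide-open) is a readout of allosteric regulation.

`ptmdyn` implements the post-analysis pipeline for comparing two
molecular-dynamics ensembles of the complex — one fully reduced, one PTMed —
and a synthetic-ensemble generator with known ground truth so every stage
can be validated without running any molecular dynamics.

## The comparison pipeline

Given matched replica ensembles of the two states (a `StatePair`), the
pipeline computes:

1. **Fluctuation statistics.** Per-residue RMSF of the Cα positions after
   rigid-body superposition, and the radius of gyration, per state.
2. **Dynamic cross-correlation.** The normalized covariance of Cα
   fluctuations, $C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
   \sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}$,
   pooled over replicas after alignment.
3. **Redistribution score.** For each residue, the fraction of partners
   with $C_{ij} > 0.2$ ($f_+$) and $C_{ij} < -0.2$ ($f_-$), both with
   strict inequalities and denominator $n-1$; the score is
   $(f_+ - f_-)_{\mathrm{PTM}} - (f_+ - f_-)_{\mathrm{reduced}}$, in
   $[-2, 2]$. Positive values mean net enrichment of correlated coupling
   upon PTM.
4. **Common-eigenspace PCA.** All frames of both states are concatenated
   after alignment, and a single Cα covariance matrix is diagonalized. The
   shared eigenvectors define one coordinate system in which each state's
   trajectories are projected; centroid shifts (mean PTM projection minus
   mean reduced projection) measure how PTM relocates the sampled
   conformations. Per-mode residue contributions are the normalized norms
   of each residue's three eigenvector components; the "top set" is the
   minimal descending-sorted prefix reaching a cumulative fraction
   (default 50%).
5. **Gate analysis.** A distance series between the lower and upper gate
   sides, classified from a Gaussian kernel density estimate: a single
   peak below 0.4 nm is closed, in [0.4, 0.7] nm open, above 0.7 nm
   wide-open, and peaks in both the closed and open bands give the
   alternating open/closed label. Band occupancies are fractions of frames
   with closed = [0, 0.4), open = [0.4, 0.7], wide-open = (0.7, ∞).
6. **Hydrogen bonds.** Geometric criteria: donor–acceptor distance
   ≤ 0.35 nm and hydrogen–donor–acceptor deviation angle ≤ 30°, backbone
   and side-chain atoms alike; occupancy is the fraction of pooled frames
   with at least one qualifying bond between a residue pair.
7. **Interaction networks.** Residue–residue nonbonded energies as direct
   Coulomb plus Lennard-Jones pair sums
   ($k_e = 332.0636$ kcal·Å/(mol·e²), Lorentz–Berthelot combination, no
   cutoff by default); pairs with |E| > 10 kcal/mol (strict) are "strong",
   and strong edges are assembled into layered flow graphs
   (regulator region → intermediate enzyme residue → gate residue),
   grouped by the subunit's gate state and labeled by charge category
   (like-charged, oppositely charged, polar/charged).
8. **Free energies.** Bennett acceptance ratio (BAR) estimates per
   alchemical λ window, chained over a two-stage schedule (electrostatics
   first, then van der Waals/bonded; 13 λ values per stage by default),
   with relative binding free energies RBFE = ΔG(protein) − ΔG(water) and
   per-PTM-type L1 summaries Σ|RBFE|.

## Tunable parameters

| Parameter | Default | Unit | Where |
|---|---|---|---|
| strong-correlation threshold | 0.2 | – | `couplingFractions()` |
| strong-interaction threshold | 10 | kcal/mol | `strongInteractions()` |
| gate band boundaries | 0.4, 0.7 | nm | `stateOccupancy()` |
| H-bond distance / angle cutoffs | 0.35 / 30 | nm / degrees | `hbondCriteria()` |
| KDE peak threshold | 10% of max | – | `classifyGate()` |
| gate distance mode | min side-chain heavy | – | `gateDefinition()` |
| PCA modes reported | 2 | – | `runCompare()` |
| BAR tolerance | 1e-10 | kT | `barEstimate()` |

All lengths are nm internally (PDB I/O converts Å at the boundary, so 3.5 Å
becomes 0.35 nm); energies are kcal/mol except alchemical work, which is
handled in kT units with an explicit `kT` conversion only at reporting.
Every default is echoed verbatim into the report a pipeline run writes.

## What the synthetic generator emulates — and what it does not

The generator replaces production molecular dynamics with four analytically
controlled ingredients:

* **Gaussian fluctuation ensembles** (`fluctuationModel()`): frames are
  independent draws around a helical Cα reference with a prescribed
  residue–residue correlation matrix, expanded isotropically to x/y/z. The
  isotropic expansion makes the recipe correlation the *exact* target DCCM,
  so recovery is testable to Monte-Carlo precision (Fisher-z standard error
  ≈ $(1-\rho^2)/\sqrt{n}$; ±0.03 is a generous band at n = 20000). An
  optional AR(1) coefficient adds frame memory but defaults off: all
  analyses under test except occupancy time series are frame-order
  invariant.
* **Markov gate dynamics** (`sampleGateSeries()`): a first-order chain over
  gate states with Normal emissions, initialized from its stationary
  distribution; hidden labels are returned as ground truth. Occupancies
  converge to the stationary vector, and with band-centered means and
  sd ≤ 0.03 nm, band and hidden-state occupancies agree within 0.03.
* **Exact gate embedding** (`embedGateInStructure()`): the designated atom
  pair's separation is set per frame to a prescribed series (within
  1e-9 nm), so gate analyses run on full trajectories with known answers.
* **Crooks-consistent work samples** (`sampleCrooksWork()`): forward
  ~ N(ΔG + σ²/2, σ²) and reverse ~ N(−ΔG + σ²/2, σ²) satisfy the Crooks
  relation exactly, making ΔG an analytic truth for BAR.

What the generator does *not* emulate: anharmonic and multi-basin
conformational landscapes, solvent and pressure coupling, force-field
physics, slow autocorrelated collective motions, and coupling between gate
state and the rest of the structure (unless embedded explicitly). Passing
tests therefore demonstrate that the *estimators* are correct and
statistically calibrated — not that desk-scale synthetic ensembles
reproduce the dynamics of a real 1500 ns simulation campaign.

## Numerical choices

* **Superposition.** Kabsch SVD with determinant correction (never a
  reflection); at least three non-collinear fit atoms are required.
  Alignment to the ensemble mean is iterated to convergence (mean-structure
  change < 1e-12, up to 50 passes) rather than a fixed pass count: a fixed
  two-pass scheme leaves the result dependent on frame order at the ~1e-7
  level, while the converged fixed point is frame-order independent up to a
  global rigid motion, which spectral quantities ignore. Replicas are first
  aligned to their own mean, then each replica's mean is rigid-fit onto the
  first replica's so pooled fluctuations live in one frame.
* **Validating correlation recovery without superposition.** Synthetic
  ensembles contain no global rigid-body motion by construction, and for
  small systems least-squares superposition itself redistributes apparent
  correlations (removing six rigid degrees of freedom from 3m coordinates
  perturbs $C_{ij}$ at O(1/m)). Recovery tests therefore run with
  `fit = FALSE`; pipeline runs on real (or embedded-gate) data keep the
  default `fit = TRUE`.
* **Eigenvector conventions.** Eigenvalues are clipped at zero; each
  eigenvector's largest-magnitude component is made positive so projections
  are reproducible. Contribution ties at the cumulative-fraction boundary
  resolve toward the lower residue index. Subunit-level projections reuse
  the complex-level eigenvectors with a chain mask rather than
  re-diagonalizing per subunit, so all subunits share one PC space.
* **BAR root finding.** The Bennett self-consistency function is monotone
  in ΔG, so the root is bracketed from the sample ranges and solved with
  Brent's method (`uniroot`) to 1e-10 kT — the same guarantee as bisection
  with Newton polish, via an established primitive. The standard error is
  Bennett's asymptotic estimate
  $\mathrm{var} = [\sum 1/(2 + 2\cosh t)]^{-1} - n_F^{-1} - n_R^{-1}$,
  which vanishes in the reversible limit and diverges without overlap;
  non-overlap is flagged (`converged = FALSE`) with the estimate still
  returned.
* **Degenerate inputs.** Residues with zero positional fluctuation get
  0-valued off-diagonal DCCM entries and are flagged rather than producing
  NaN. A degenerate (all-frames-identical) ensemble yields all-zero
  eigenvalues and zero variance fractions. A residue without side-chain
  heavy atoms (one-bead fixtures) falls back to all heavy atoms for gate
  distances.
* **Boundary conventions.** Strict inequalities at ±0.2 for strong
  correlation and at ±10 kcal/mol for strong interactions (the stated
  thresholds are open bounds); gate band boundaries 0.4 and 0.7 nm are
  owned by the open band (closed means peaks *below* 0.4, wide-open peaks
  *above* 0.7).

## Design choices where the design was open

* **Residue identity.** Residue numbering is 1-based per chain and taken
  verbatim from the topology. Selections accept both chain-qualified keys
  ("A:33") and bare indices ("33"); a bare index matches the residue in
  every chain that has it, which is the natural way to address gate
  residues present in all four enzyme subunits. Reports always use
  chain-qualified labels.
* **Gate distance atoms.** Which atoms carry the "upper–lower" distance is
  explicit configuration: the default takes the minimum distance between
  side-chain heavy atoms of the two sides; a centroid mode is available,
  and outputs record the mode used.
* **H-bond angle vertex.** The 30° cutoff is applied to the
  hydrogen–donor–acceptor angle at the donor (the GROMACS-style
  deviation-from-linearity convention).
* **Occupancy reporting.** All three bands are reported, plus a merged
  open + wide-open fraction, since summaries that show only "open vs
  closed" may merge the two open-like bands.
* **L1 reference.** The Manhattan summary of a PTM type's RBFEs is taken
  from the zero vector: Σ|RBFE| over that type's sites.
* **Charge classes.** ASP/GLU negative, ARG/LYS positive, HIS
  polar/uncharged by default (configurable positive); edges with neither
  partner charged are categorized "other" and excluded from charge-flow
  output. Repulsive (positive) strong interactions are retained and
  labeled, not dropped.
* **Plan enumeration.** The reduced baseline counts as one system
  regardless of replica expansion (replicas expand last), and disulfide
  systems — which pair two sites — are specified explicitly rather than
  enumerated per site.

## Problem sizes

Validation runs at desk scale: correlation recovery uses 8–12 residue
ensembles of 20000 frames; PCA covariance recovery pools 50000 frames of a
single residue with a known 3×3 covariance; gate occupancies use
50000-step Markov chains; BAR coverage uses 200 seeded repetitions of 10⁵
work samples per direction over ΔG ∈ {−2, 0, 5} kT and σ ∈ {0.5, 1, 2} kT;
the end-to-end pipeline fixture uses 10–20 residues, 2–3 replicas and
120–400 frames per replica. These sizes give Monte-Carlo error comfortably
inside each stated tolerance while keeping the full suite in minutes.

## A worked fixture run

```{r, eval = FALSE}
dir <- tempfile(); out <- tempfile()
runSimulate(list(), dir)                      # default study-like fixture
cfg <- list(
  topology = file.path(dir, "topology.tsv"),
  trajectories = list(
    reduced = file.path(dir, paste0("reduced_rep", 1:3, ".pdb")),
    ptm = file.path(dir, paste0("ptm_rep", 1:3, ".pdb"))),
  gate = list(lower = 5, upper = 15, chains = "A"))
report <- runCompare(cfg, out)
utils::read.csv(file.path(out, "redistribution_score.csv"))
```

## Known limitations

* Frames are treated as independent; no statistical-inefficiency or
  autocorrelation correction is applied to occupancy or fluctuation
  uncertainties.
* Nonbonded energies are vacuum/uniform-dielectric pair sums — no
  Poisson–Boltzmann or generalized-Born solvation, so absolute energies
  are not comparable to solvated estimates, only differences and
  threshold-crossing patterns.
* No periodic-boundary imaging: input coordinates are assumed whole.
* The KDE peak classification is a heuristic; heavily overlapping bands or
  very broad distributions can merge peaks. The 10% relative peak
  threshold suppresses noise bumps but is not adaptive.
* MBAR/TI-quadrature estimators, time-lagged component analysis and
  free-energy surfaces over PCs are out of scope.
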