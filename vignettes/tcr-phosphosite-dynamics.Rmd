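---
title: "Modeling early TCR/CD28 phosphosite dynamics with tcrphosdyn"
author: "tcrphosdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early TCR/CD28 phosphosite dynamics with tcrphosdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrphosdyn)
```

## Scope

`tcrphosdyn` studies the first minute of T-cell receptor (TCR) and CD28
co-stimulation at the resolution of individual phosphotyrosine (pTyr)
sites.  It combines three strands:

1. a **rule-based kinetic model** of proximal TCR/CD28 signaling,
   simulated with a network-free, particle-based stochastic algorithm,
   with in-silico knockdowns of PTPN6 (SHP-1) and LCP2 (SLP-76);
2. a **phosphoproteomic time-course pipeline** for SILAC ratio tables
   sampled at 5, 15, 30 and 60 s after stimulation, relative to
   unstimulated cells;
3. **synthetic-data generators** with planted ground truth, so that
   every stage — regulation filtering, clustering, classification,
   enrichment, parameter fitting — can be validated end to end without
   any external download.

## The rule-based model and its simulator

### Model dialect

Models are written in a subset of the BioNetGen language (BNGL):
`parameters`, `molecule types`, `seed species`, `observables` and
`reaction rules` blocks.  Components may declare state alphabets
(`y188~U~P`); pTyr sites use the two-state alphabet `{U, P}`.  In
patterns, a component written without a bond mark must be *unbound*,
`!+` means bound to anything, `!?` leaves the bond unconstrained, and
an omitted component is unconstrained; paired integer labels (`!1`)
name explicit bonds.  Rules are irreversible mass-action arrows whose
transformation is inferred by diffing the two sides and must be exactly
one of: form one bond, break one bond, or change one component state.
Everything else — compartments, functional rate laws, synthesis and
degradation, reversible arrows — is rejected with a line-numbered
error rather than skipped: a silently subsetted model is a wrong model.
The writer emits canonical text (alphabetical ordering, renumbered bond
labels), which is what makes parse/write round-trips testable.

Location tags (`E`, `M`, `C` for extracellular, membrane, cytosol) are
annotations only.  The simulation volume is a single well-mixed
compartment, and bimolecular rate constants are given directly in
events per second per reactant pair (copy-number units); no volume
conversion is performed because no volumes are modeled.

### Network-free simulation

The simulator never enumerates the reaction network.  It keeps the
explicit particle state (every molecule with its component states and
bonds) and matches rule patterns against it:

* **Embeddings.**  Reactant patterns are connected site graphs.  An
  embedding is determined by the molecule matched to the first pattern
  molecule (the anchor); the remaining pattern molecules are reached by
  following labelled bonds.  The engine maintains one match flag per
  (pattern, candidate anchor) and, after each event, refreshes only
  molecules within two bonds of the event — this is what keeps a
  65-rule model with a few thousand particles fast.
* **Symmetry convention.**  Match counts are embedding counts divided
  by the pattern's automorphism order, so the symmetric homodimer
  pattern `A(a!1).A(a!1)` counts a single dimer once.  This matches the
  mass-action convention.
* **Propensities.**  Unimolecular rules contribute `k * matches`;
  bimolecular rules `k * m1 * m2`, and `k * m * (m - 1)` ordered
  pairings when the two reactant patterns are syntactically identical.
  When two *distinct* reactant patterns happen to select embeddings
  sharing a molecule (e.g. a kinase acting on its own type in trans),
  the event is executed as a null event — time advances, nothing
  changes — rather than correcting the propensity; for the models in
  this package such overlaps are rare to impossible, and the
  convention is exercised by tests.
* **Stepping.**  Gillespie's direct method: waiting times are
  exponential in the total propensity, rules are chosen proportionally
  to theirs, and one uniformly chosen embedding is transformed.
  Observables are recorded by exact-time sampling: the state at a grid
  time is the state just before the first event beyond it.  When the
  total propensity is zero the simulation jumps to the next
  observation time.
* **Equilibration and stimulation.**  Each run first relaxes the
  stimulus-free model for `t_eq` seconds to its unstimulated steady
  state, then injects the stimulus species at `t = 0` and records the
  grid `{0, 5, 15, 30, 60}` s.  The default `t_eq = 300` s passes the
  doubling self-consistency check (doubling `t_eq` leaves the t = 0
  observations unchanged within Monte Carlo error) for the shipped
  models.
* **Reproducibility.**  All randomness flows through R's RNG; run *r*
  of an ensemble uses `seed + r - 1`, and identical
  (model, protocol, seed) give bit-identical trajectories.

Because the model is a single cell while measurements average many
cells, ensembles of runs are averaged (`average_runs()`); the package
default is 100 runs, and the test suite uses 30–50 where the checked
quantity is a direction rather than a magnitude.

## The TCR/CD28 network

The shipped model covers ten proteins carrying the sixteen measured
pTyr-site observables — CD3G, LCK (Y192, Y394, Y505), ZAP70 (Y292,
Y319, Y493), LAT (Y132, Y191, Y226), PLCG1, WAS, PTPN6, PAG1, DOK1,
DOK2 — plus seven additional proteins required for their regulation
(CD3E, CD247, CD28, CSK, NCK, GRAP2, LCP2) and a stimulus species
representing pre-crosslinked anti-CD3/anti-CD28 antibody.  The roster
is a reconstruction: it covers the pTyr sites with well-characterized
roles in proximal TCR signaling and known kinases, phosphatases or
binding partners, and it enforces a fixed composition of 16 measured
sites on exactly 10 proteins plus 7 additional proteins.  RASA1, a passive reader of DOK2 pY299, is not
an explicit molecule: its presence would not alter any site's dynamics
and the additional-protein count is kept at seven.

Site classes follow the mechanism, and the mechanism follows the class:

* **Class 1** — phosphorylated without prior receptor phosphorylation:
  CD3G Y171, LCK Y394, PTPN6 Y566, WAS Y291 (and the unmeasured CD3E
  Y188 and CD247 ITAM).  CD28 recruits LCK constitutively; once the
  crosslinker engages CD28, the CD28-bound LCK trans-autophosphorylates
  its activation loop (Y394) provided the inhibitory C-terminal Y505 is
  unphosphorylated, and active LCK phosphorylates these sites directly.
* **Class 2** — requires ITAM phosphorylation: ZAP70 docks its SH2 on
  the phosphorylated CD247 ITAM and only docked ZAP70 is an LCK
  substrate (Y493 and the regulatory Y292/Y319); active ZAP70 then
  phosphorylates LAT and LCP2, and phospho-LCP2 drives PLCG1 Y783.
* **Class 3** — dephosphorylated upon stimulation: LCK Y192 and Y505,
  PAG1 Y163, DOK1 Y449, DOK2 Y299.  These carry basal phosphorylation
  pressure at rest; LCK-activated PTPN6 dephosphorylates Y192, Y163,
  Y449 and Y299.  Because PAG1 pY163 and DOK1 pY449 recruit CSK, which
  phosphorylates LCK Y505, PTPN6 activation releases CSK and lets a
  CD45-like background activity clear Y505 — the positive feedback
  that makes a phosphatase an accelerator of early signaling.  A
  toggle (`ptpn6_direct_y505`) adds direct PTPN6 action on Y505; the
  default keeps the indirect route only, matching the modeled
  feedback narrative, even though direct dephosphorylation is
  biochemically possible.

The **shortcut** to WAS: the NCK N-terminal SH3 binds the CD3E
proline-rich sequence while CD3E Y188 is unphosphorylated (the two are
mutually exclusive because the PRS overlaps Y188).  NCK carries WAS via
its C-terminal SH3, so WAS sits receptor-proximal *before* any ITAM
signaling and is phosphorylated as soon as LCK activates — earlier
than ZAP70 Y493.  As Y188 becomes phosphorylated the shortcut
disengages while the long LAT–GRAP2–LCP2 route recruits NCK instead.
Disabling the shortcut (`shortcut_enabled = FALSE`) removes only the
NCK–CD3E binding rules; the shortcut WAS-phosphorylation rule remains
but can never fire, so every other rule is untouched.

ITAM granularity is deliberately coarse: one representative ITAM
tyrosine per modeled chain (CD247 Y142 as the ZAP70 dock, CD3E Y188
explicit because the PRS overlap requires it, CD3G Y171 as the class-1
example).  Enumerating all ten TCR ITAM tyrosines would multiply state
without changing any readout this package reports.

### Parameters

`default_tcr_params()` is a *reconstructed* table: association rates of
order 10^-4^–10^-3^ per pair per second, catalytic and background
rates of order 10^-3^–10^-1^ s^-1^, and copy numbers of order
10^2^–10^3^ per cell.  The rate values were calibrated with the
package's own fitting machinery so that the model reproduces four
experimentally established behavior families (WAS before ZAP70;
the PTPN6-knockdown directions; LCP2-knockdown ablation of PLCG1 with
retained WAS; shortcut disengagement and delay).  The copy numbers are
smaller than literature per-cell abundances by roughly an order of
magnitude: this is a problem-size choice that keeps a single-cell
trajectory at ~2 × 10^4^ events so that 100-run ensembles for four
genotypes complete in minutes, and it leaves all relative readouts
(fold changes, AUC ratios, orderings) unchanged in kind.  None of the
numbers should be read as measured constants.

### Derived readouts

Relative time courses divide each observable by its unstimulated
baseline; knockdown ensembles are normalized by the *wild-type*
baseline so genotypes are comparable (when a baseline is exactly zero a
pseudocount of 0.5 is added to numerator and denominator).  Cumulative
phosphorylation is the trapezoidal area of the relative course over
0–60 s.  Endpoint scaling divides by the 60-s value for shape
comparisons, and the half-rise time linearly interpolates the first
crossing of the midpoint between initial and maximal value.  The
"WAS retains at least 50 % of its wild-type cumulative response under
LCP2 knockdown" check operationalizes the qualitative observation that
early WAS phosphorylation survives LCP2 depletion; the 50 % threshold
is a convention of this package.

## The phosphoproteomic pipeline

Input is a plain TSV with one row per (phosphopeptide, replicate) and
abundance ratios at 5/15/30/60 s versus 0 s.

* **Proline correction.**  Arginine-to-proline conversion in SILAC
  depresses heavy/light ratios of proline-containing peptides.  The
  original normalization procedure is not specified quantitatively, so
  the correction here is a documented reconstruction — each ratio is
  multiplied by `(1 - f)^(-n_proline)` — with default `f = 0`, i.e.
  off unless configured.
* **Site collapse.**  When several peptides cover a site, the least
  modified peptide (minimal number of phospho groups) represents its
  dynamics; ties break to the shortest, then lexicographically
  smallest, sequence.
* **Averaging.**  Arithmetic mean over the replicates in which a value
  was detected; missing values are skipped, never imputed, and the
  contributing replicate count is recorded.  A site missing at a time
  point in all replicates has no mean there and cannot qualify as
  regulated at that time point.
* **Regulation filter.**  A site is regulated when any time point
  shows a mean ratio of at least θ = 2 or at most 1/θ.  The boundary
  is included (`>=`) by default because that is the stricter-sourced
  wording; a strict comparator is available as configuration since the
  study's own text uses both.
* **Clustering.**  Fuzzy c-means with c = 4 clusters, fuzzifier
  m = 2, tolerance 10^-6^, at most 500 iterations, on log2 profiles
  that are anchored at the t = 0 baseline (log2 ratio 0) and z-scored
  per site.  The baseline anchor matters: without it, z-scoring erases
  the rise timing that distinguishes fast from delayed responders.
  Initial centers are distinct profiles sampled under the given seed,
  making the result deterministic; the clustering itself is the
  standard fuzzy c-means implementation from `e1071`.  Clustering
  tools differ in their default standardization and stopping rules,
  so membership-level agreement with any particular tool is not
  promised — recovery is instead demonstrated against planted
  synthetic archetypes.
* **PCA classes.**  For model-guiding site classification the profiles
  are projected on their first two principal components and split by
  seeded k-means (k = 3); the cluster whose mean course decreases is
  class 3, and of the increasing clusters the one with the earlier
  half-rise is class 1.  This algorithmic operationalization (rather
  than visual delineation) is a convention of the package.
* **Enrichment.**  One-sided Fisher exact test (over-representation)
  of each annotation term in a cluster against detected-but-unregulated
  background proteins, Benjamini–Hochberg adjustment across terms
  within the cluster, and reporting restricted to terms occurring at
  least twice in the cluster with adjusted p < 0.05.  Annotations are
  user-supplied tables (protein, term); no live ontology retrieval is
  performed.

## The synthetic generator

`generate_ratio_table()` emulates the statistical structure of a
three-replicate SILAC pTyr time course: four regulated temporal
archetypes (fast-up reaching the threshold by 5 s, slow-up by 30 s,
down below 1/θ, transient above θ early and back below it by 60 s)
plus an unregulated profile strictly inside (1/θ, θ); multiplicative
log-normal noise with σ = 0.3 log2 units per measurement; and
independent per-replicate, per-time-point detection dropout with
probability 0.8 of detection, which produces the partial overlap of
peptides across replicate experiments.  σ and the dropout rate are
conventions chosen to resemble the reported replicate scatter and
overlap, not values stated anywhere.

The generator does **not** emulate intensity-dependent missingness,
peptide-level quantification error structure, site-localization
ambiguity, or correlated noise across sites.  Passing the recovery
tests therefore shows that the pipeline's logic is correct under the
stated noise model — not that it would perform identically on real
spectra.

`generate_truth_dataset()` plays the same role for fitting: it
simulates a model at known parameters, converts to relative courses,
and applies log-normal noise, returning the generating parameters as
the recovery target.

## Parameter fitting

The objective simulates the model at proposed parameters and sums
squared differences of log2 relative phosphorylation against the log2
measured means over all sites and times — log2 so that up- and
down-regulation weigh symmetrically.  Every evaluation reuses the same
per-run seeds (common random numbers), which turns the stochastic
objective into a deterministic function of the parameters and makes
descent meaningful.  Estimation is a coarse grid search (all points,
common seeds, first-in-enumeration tie-break) followed by
quasi-Newton refinement: L-BFGS-B with finite-difference gradients,
box bounds handled natively, positivity-only parameters optimized in
log space, and a final projection guard.  The finite-difference step
is 0.05 (in the transformed coordinates) — deliberately large,
because the CRN objective is piecewise constant at the resolution of
single reaction events and tiny steps would differentiate that
discreteness instead of the trend.  The refined result never reports
a worse objective than its start or than the grid stage.

The shipped recovery experiment (`toy_recovery_experiment()`) fits the
two rate constants of a ligand-induced phosphorylation cycle from
noisy relative courses (per-measurement σ = 0.1, three replicate
measurements averaged per point, mirroring the triplicate experimental
design) observed on a dense 0–60 s grid under *two* stimulus doses.
The two doses are the important design element: with a single dose,
amplitude and timescale constrain only a combination of the two
constants and the estimate is ill-conditioned; the second dose breaks
that degeneracy.  Refinement is multistarted from the three best grid
points, because a single coarse grid cell can trap the descent in a
shallow side basin of the CRN objective.  Under this design, recovery
lands within 25 % of truth.  Tests run it at 30 runs per evaluation,
the acceptance script at 50.

## Numerical and degenerate-input conventions

* Flat (zero-variance) profiles cannot be z-scored and are rejected as
  degenerate; clustering requires at least c distinct profiles.
* Zero baselines in relative courses use the ε = 0.5 pseudocount rule;
  zero 60-s endpoints make endpoint scaling an error.
* Grid-search ties break to the first point enumerated; k-means for
  the PCA classes uses 25 restarts under the caller's seed.
* The simulator caps runaway trajectories at 2 × 10^8^ events and
  reports quiescence instead of dividing by a zero total propensity.

## Limitations

The model is deliberately proximal: no Ras/MAPK, calcium or NFAT
branches, no receptor clustering, kinetic proofreading or
antigen-affinity discrimination.  Parameter values are reconstructed,
calibrated to directions rather than magnitudes, and copy numbers are
scaled down; quantitative predictions (absolute site occupancies,
absolute AUCs) are outside what this package claims.  The pipeline's
statistical guarantees are demonstrated on the synthetic noise model
described above.
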