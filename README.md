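# tcrphosdyn

Rule-based modeling and phosphoproteomic analysis of the first minute of
T-cell receptor (TCR) / CD28 co-stimulation.

Within seconds of antigen-receptor engagement, T cells reshape their
tyrosine phosphoproteome: some phosphosites rise almost immediately,
others only after the receptor ITAMs are phosphorylated, and a set of
inhibitory sites is actively *de*phosphorylated.  `tcrphosdyn` is for
systems biologists who want to study this window quantitatively.  It
provides:

- **A rule-based single-cell kinetic model** of proximal TCR/CD28
  signaling (CD3 chains, LCK, ZAP70, LAT, LCP2, PLCG1, WAS, PTPN6,
  PAG1, DOK1/2, CSK, NCK, GRAP2), including the PTPN6 (SHP-1)
  positive-feedback loops — LCK activates PTPN6, PTPN6 clears the
  inhibitory sites LCK Y192, PAG1 Y163, DOK1 Y449, DOK2 Y299, and CSK
  release lets LCK Y505 decay — and the NCK–CD3E proline-rich-sequence
  "shortcut" that places WAS at the receptor before ZAP70 is active.
- **A network-free stochastic simulator** (Gillespie direct method over
  rule embeddings, in C++): models are written in a BNGL subset, never
  expanded to a reaction network, equilibrated to the unstimulated
  steady state, stimulated at t = 0, and observed on the
  {0, 5, 15, 30, 60} s grid.  Knockdowns are modeled by setting a
  protein's copy number to zero.
- **A SILAC phosphoproteomic pipeline**: proline-conversion correction,
  least-modified-peptide site collapse, replicate averaging, ≥2-fold
  regulation filtering with direction and earliest-change timing, fuzzy
  c-means clustering of temporal profiles, PCA-based assignment of the
  three mechanistic site classes, and Fisher/Benjamini–Hochberg term
  enrichment against detected-but-unregulated backgrounds.
- **Parameter estimation**: a common-random-numbers least-squares
  objective on log2 relative phosphorylation, coarse grid search, and
  quasi-Newton (variable-metric) refinement with bounds.
- **Synthetic-data generators** with planted ground truth (temporal
  archetypes, log-normal noise, replicate dropout) so every stage is
  testable offline.

The propensity of a rule with rate constant *k* is *k·m* for one
reactant pattern and *k·m₁·m₂* for two (with *m(m−1)* ordered pairings
for identical patterns), where the match count *m* is the number of
embeddings of the pattern site-graph into the current mixture divided
by the pattern's automorphism order.  Waiting times are
Exponential(total propensity); one uniformly chosen embedding of the
selected rule is transformed per event.

## Worked example

```r
library(tcrphosdyn)

params   <- default_tcr_params()
model    <- build_tcr_model(params)            # validated model_spec
protocol <- tcr_protocol(params, n_runs = 30, seed = 1)

wt <- average_runs(simulate_ensemble(model, protocol))
kd <- average_runs(simulate_ensemble(apply_knockdown(model, "PTPN6"),
                                     protocol))

relative_timecourse(wt, "WAS_Y291")
#> relative_timecourse WAS_Y291: 0 s: 1, 5 s: 2.01, 15 s: 4.38, 30 s: 6.48, 60 s: 8.39
relative_timecourse(wt, "ZAP70_Y493")
#> relative_timecourse ZAP70_Y493: 0 s: 1, 5 s: 2.3, 15 s: 7.59, 30 s: 19.6, 60 s: 37.1
```

WAS Y291 doubles already at 5 s and half-rises at **17.2 s**, while
ZAP70 Y493 — which must wait for ITAM phosphorylation and SH2 docking —
half-rises at **29.4 s**: the shortcut pathway makes the actin
regulator respond *before* the canonical kinase cascade.  Comparing
cumulative (0–60 s) phosphorylation against the wild-type baseline:

```r
b <- wt$mean[1, "LCK_Y192"]
cumulative_auc(relative_timecourse(wt, "LCK_Y192", baseline = b))   # 27.1
cumulative_auc(relative_timecourse(kd, "LCK_Y192", baseline = b))   # 184.6
```

Without PTPN6 the inhibitory LCK Y192 site is never cleared, and its
cumulative phosphorylation rises almost seven-fold — the phosphatase
acts as an accelerator of early signaling.

The same analyses are scriptable from a shell via the thin CLI in
`inst/cli/tcr-phosdyn` (subcommands `generate`, `analyze`, `simulate`,
`kd-experiment`, `fit`; every output file records its command, seed and
package version in a header line).

For the model dialect, simulator conventions, pipeline settings and
design rationale, see the methods vignette
(`vignettes/tcr-phosphosite-dynamics.Rmd`).

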