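---
title: "Modelling the coupled IRF3/NF-kB/JAK-STAT innate immune response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the coupled IRF3/NF-kB/JAK-STAT innate immune response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innatesim)
```

# The biological system and the model

Mouse embryonic fibroblasts discriminate bacterial from viral signals with
one regulatory network built from three transcription-factor arms. Bacterial
lipopolysaccharide (LPS) transiently activates IKK, which degrades IkBa and
releases NF-kB into the nucleus; NF-kB induces its own inhibitors IkBa and
A20, and these two negative feedbacks terminate the pulse within about an
hour and a half. The viral mimic poly(I:C), delivered by lipofection, is
sensed in the cytoplasm by RIG-I and activates both IKK (hence NF-kB) and
TBK1 (hence IRF3). Nuclear NF-kB and nuclear phospho-IRF3 are *jointly*
required to switch on the *Ifnb1* gene; secreted IFN-beta then acts through
IFNAR and JAK/STAT to induce the interferon-stimulated sensors and effectors
(RIG-I, PKR, OAS1A, STAT1/2, SOCS1). Poly(I:C)-activated PKR and OAS1A
suppress the synthesis of IkBa and A20 — PKR by inhibiting their
translation, OAS1A by degrading their mRNAs — so in cells with enough
sensor protein the negative feedbacks collapse and NF-kB/IRF3 activity
locks in for many hours instead of pulsing. SOCS1 closes a slower negative
loop by inhibiting IFNAR, which shapes the phospho-STAT1 peak and allows
long-lasting priming: IFN-beta-pretreated cells carry elevated RIG-I, PKR
and OAS1A for a long time while transcription of those genes has already
shut down.

`innatesim` implements this network as a single stochastic reaction system
(62 species, 115 reactions) with three interchangeable engines:

* **SSA** — the Gillespie direct method (exact; the default), with
  propensity updates restricted to the reaction dependency graph and
  block-sum reaction selection;
* **tau-leaping** — an approximate accelerated integrator, tagged `tau` in
  every trajectory it produces;
* **ODE** — the mean-field equations built from the same propensity
  functions, with gene states replaced by continuous ON-allele occupancies
  (`deSolve::lsoda`).

## Bursty genes and population heterogeneity

Every regulated gene (*Nfkbia*, *Tnfaip3*, *Ifnb1*, *Stat1*, *Stat2*,
*Ddx58*, *Eif2ak2*, *Oas1a*, *Socs1*) is a two-state (telegraph) locus with
two independently switching alleles. Switch-on propensities are linear in
the activating factor's nuclear abundance — the simplest form consistent
with switching driven by transcription-factor binding and dissociation; the
*Ifnb1* locus uses the product of nuclear NF-kB and nuclear phospho-IRF3
counts, so its activated switch-on propensity is zero unless both are
present (the AND gate).

Population heterogeneity has exactly two sources, matching the experimental
analysis: (i) transcriptional bursting during the prestimulation phase,
which broadens the initial distributions of RIG-I, PKR and OAS1A, and (ii)
uneven poly(I:C) uptake between cells, modelled as i.i.d. log-normal boluses
with mean proportional to dose and coefficient of variation 0.8 (a broad,
right-skewed distribution typical of lipofection). The bolus enters the
cytoplasm with a first-order rate (half-time ~40 min), so intracellular
poly(I:C) peaks within the first few hours and then decays.

## Parameterization

All rate constants ship as a named vector (`default_params()`), each value
tagged with its provenance. The defaults are calibrated against the study's
printed quantitative anchors rather than fitted to raw data:

* basal stationary mRNA means of 10 copies/cell for *Ddx58* and *Eif2ak2*
  and 1 copy/cell for *Oas1a* and *Ifnb1* (set in closed form through the
  telegraph stationary law);
* a mean-field nuclear NF-kB response to 1 ug/ml LPS peaking near 40 min
  and terminating (below 20% of peak over baseline) near 1.5 h;
* ~40% NF-kB-responding and ~25% IRF3-responding cells in the 4–10 h window
  after 1 ug/ml poly(I:C), with IRF3 activation the harder of the two
  (A20 inhibits TBK1 more strongly than IKK);
* ensemble-mean *Ifnb1* mRNA peaking before 6 h, phospho-STAT1 before 10 h,
  and total STAT1 still accumulating at 24 h (slow STAT turnover plus the
  SOCS1 brake).

Copy numbers follow the mammalian-cell convention: abundant signalling
proteins (NF-kB, IKK, IkBa, STATs) at 1e4–1e5 molecules per cell,
interferon-stimulated sensors at 1e1–1e3. NF-kB, IKK, TBK1, IRF3 and IFNAR
totals are conserved (no synthesis/turnover terms), which keeps total
NF-kB exactly constant along any stochastic path — a property the test
suite asserts — and concentrates the computational effort on the regulated
species. Doses map to molecule counts through explicit conversion
constants; "1000 U/ml" IFN-beta maps to a receptor-saturating extracellular
amount (about 50 times the half-saturation of IFNAR binding). The
extracellular compartment is the cell's 8 nl aliquot of culture medium
(200 ul above ~25,000 cells).

## Stimulation protocols and genotypes

`make_protocol()` validates ordered event lists (LPS, poly(I:C)
transfection, IFN-beta, cycloheximide, the PKR inhibitor C16, IFNAR
blocking, release); `protocol_preset()` provides the canonical designs,
including IFN-beta priming for 24 h followed by poly(I:C), cycloheximide
1 h before LPS, C16 1 h before poly(I:C), and IFNAR-blocking antibody
re-dosed at 0/3/6/10 h. Cycloheximide zeroes all translation propensities
from its addition time; C16 scales PKR activation to 20% (partial
inhibition); the blocking antibody zeroes IFN-beta/IFNAR binding.
Knockouts zero the corresponding protein's synthesis and remove it from the
initial state: `RelA_knockout` removes every NF-kB pool, `Stat1_knockout`
removes STAT1 so no STAT1/2 heterodimer — the model's sole STAT
transcription factor — can form. (STAT2 homodimers are deliberately
omitted: keeping the heterodimer as the only active species makes STAT1
loss abolish all ISG induction, which is what the knockout data show.)

## Exactness across protocol events, and the shared medium

Protocol events are propensity/state changepoints. The SSA carries one
unit-rate exponential quantum across each changepoint, decrementing it by
`a0 * dt` when a boundary is crossed instead of redrawing the waiting time.
This is exact for time-varying jump processes, and it has a useful side
effect: a changepoint that does not alter any propensity leaves the sample
path bit-identical. Ensembles exploit this in `medium_mode = "shared"`,
where cells advance in 60 s chunks and their secreted IFN-beta is pooled
into one well-mixed compartment (volume n_cells x 8 nl, fractional
molecules kept in a reservoir): with one cell the synchronisation points
are no-ops and shared mode coincides exactly with the default autocrine
(`per_cell`) mode. The default is `per_cell` — population averages are then
averages of independent simulations, matching how the reference
simulations were averaged — while shared mode exposes the paracrine
physics for exploration.

RNG: PCG32 with one independent stream per cell keyed by (master seed,
cell index), so ensembles are reproducible and cells are independent
regardless of execution order; the 128-bit generator state travels with
the path, which is what allows chunked execution without breaking
reproducibility.

## Equilibration

The canonical configuration precedes every stimulation by a 3e6 s (~35 day)
unstimulated phase so that gene states, mRNAs and proteins reach their
bursty stationary distributions. `equilibrate(mode = "full")` runs that
phase with the exact SSA. Because the full phase costs ~1e8 events per
cell, ensembles default to `mode = "fast"`: allele states are drawn from
the telegraph stationary occupancy, mRNA counts from a moment-matched
negative binomial, and the burst-driven sensor proteins (RIG-I, PKR,
OAS1A) from laws matched to the stationary mean and linear-noise variance
of the gene-to-mRNA-to-protein cascade (obtained from the 3x3 stationary
Lyapunov equation — exact second moments here, since the cascade is
linear); all remaining pools start at the deterministic basal state. The
test suite compares fast against full marginals by Kolmogorov–Smirnov test
(Bonferroni-corrected over species) on a shortened full phase of 1.2e5 s —
several autocorrelation times of the slowest sampled pool — with 80 cells
per arm; the acceptance suite adds a full-SSA spot check of an isolated
locus over the complete 3e6 s phase. Fast mode samples marginals
independently and therefore discards gene–mRNA–protein correlations within
a cascade; this is invisible to the marginal checks and to window-averaged
ensemble statistics, but analyses of fine-grained burst timing should use
full equilibration.

## Read-outs

Nuclear translocation of a stained nucleus is scored from summed channel
intensities with three normalisation cases: background-corrected and
image-normalised (Case 1, used for RelA and IRF3), background-corrected
only (Case 2, for p-STAT1, whose cellular abundance changes), and raw
(Case 3, live-cell time-lapse). The overall-image correction area is taken
as the whole image; the source formulas leave the support of the
image-level sums ambiguous, and the whole-image choice makes Case 1 exactly
gain-invariant, which the tests assert. For simulated cells the score is
the nuclear fraction of the factor (nuclear/total), which puts simulation
and staining on one classifier. A cell *responds* for a factor when its
score exceeds the 0.95 quantile of non-treated control scores (the cut-off
quantile is not printed in the source; 0.95 is this package's choice, with
a small absolute guard band of 0.05 on the simulated-score scale because
basal nuclear IRF3 is essentially zero and its control quantile alone would
be degenerate). A cell is *active* when it responds with both NF-kB and
IRF3. Window fractions average scores over 4–10 h before thresholding.
Profile features use the earliest argmax for peaks (ties break to the
earliest time) and define termination as the first post-peak crossing of
baseline + 0.2 x (peak - baseline).

The dPCR calibration layer converts between relative RT-PCR delta-CT
values (target CT minus GAPDH CT, so higher expression means lower
delta-CT) and absolute copies per cell through the per-gene coefficient
`Q = mean(log2(copies) + dCT)` over paired lysates; `copies = 2^(Q - dCT)`
and its exact inverse move profiles between the two scales, and genes
without dPCR pairs fall back to the mean Q of the calibrated genes.

## Synthetic data

`gen_translocation_dataset()` draws bimodal per-cell score tables from a
two-component log-normal mixture (scores are intensity ratios, hence
strictly positive) with a configurable joint-responder fraction and a
label-correlation parameter that controls how many cells respond with only
one factor; the default correlation is high because most IRF3 responders
also show NF-kB translocation. `gen_rtpcr_dataset()` adds Gaussian
replicate noise in CT units (default s.d. 0.8, the observed replicate
variability of the GAPDH reference) to calibrated mean profiles.
`gen_uptake_dataset()` adds multiplicative measurement noise to uptake
draws. All generators are seed-reproducible and return ground truth for
recovery tests. Bimodality of generated histograms is checked by
Gaussian-mixture model selection (BIC, one vs two components) on the log
scale.

# Numerical choices and problem sizes

* SSA reaction selection uses 16-wide block sums with periodic full
  propensity refresh (every 2^20 events) to cap floating-point drift; any
  drift-induced mis-selection triggers an immediate full recompute.
* Negative counts are impossible by construction and are asserted, never
  clamped; tau-leaping re-draws a halved step if a leap would go negative,
  and falls back to near-exact stepping when the step shrinks to ~1/a0.
* The ODE engine integrates piecewise between changepoints (lsoda,
  rtol 1e-6, atol 1e-3 by default) and restarts cleanly at each event.
* Reported simulation sizes are chosen to match the study conditions where
  stated — 50-cell ensembles for responding fractions, 200 cells for basal
  expression, the 4–10 h scoring window, 3e6 s equilibration for the
  single-locus spot check — and otherwise to keep Monte-Carlo error well
  inside the tolerance being checked (e.g. 24–25 cells for ordering
  comparisons, where effects are tens of percentage points).
* Trajectory output samples the jump path piecewise-constantly: each grid
  point records the state just before that time (60 s default spacing; the
  source does not state its plotting interval).

# Known limitations

* The deterministic (mean-field) cell is *not* representative of the
  poly(I:C) response: with ~40% of cells responding, the ODE trajectory
  differs from both single stochastic paths and the ensemble mean — a
  feature of the biology the model reproduces, not a numerical artefact.
* Apoptosis, AP-1/c-Jun dynamics, TLR3/MDA5 receptor branches and
  ISGF3-driven *Ifnb1* feedback are outside the model's scope.
* The shared-medium mode is well-mixed: no spatial gradients, diffusion or
  cell division/death.
* Rate constants are calibrated to printed population-level anchors, not
  fitted to raw single-cell data; quantities far from those anchors (e.g.
  absolute phospho-protein levels) are order-of-magnitude only.
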