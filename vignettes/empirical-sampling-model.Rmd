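---
title: "An empirical-sampling model of stem-like and bulk cancer cell growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An empirical-sampling model of stem-like and bulk cancer cell growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscsim)
```

## The model

`cscsim` treats a mixed cancer cell population as a discrete-time multi-type
branching process. The population is partitioned into $l$ distinguishable
states $\lambda \in \{1, \dots, l\}$ — in the motivating system, ALDH+
stem-like cells and ALDH− bulk cells of an ovarian cancer population — with
counts $c_\lambda(t)$ observed at multiples of a fixed period $h$, the
duration of a single-cell microfluidic chamber experiment (72 h for the
SKOV3 cell line, 120 h for primary cells).

What makes the model unusual is that the offspring law is not a parametric
family. Each viable single cell captured in a chamber yields one observation:
the vector $u_\lambda^* = (u_{\lambda 1}^*, \dots, u_{\lambda l}^*)$ of
progeny it produced per type over one period, *excluding the parent cell
itself* (a live but non-dividing — quiescent — parent scores the zero
vector). The collection of these vectors, with their observed frequencies, is
the model: forward simulation resamples chamber outcomes verbatim, weighted
by frequency. No growth rate, division symmetry, or transition probability is
ever fitted.

One simulation step works per parent cell of type $\lambda$:

$$
q_\lambda^* =
\begin{cases}
O_\lambda = (0, \dots, 0) & \text{with probability } g_\lambda(t+1) \\
u_\lambda^* \;(+\; e_\lambda \text{ if the parent is retained}) & \text{with probability } 1 - g_\lambda(t+1),
\end{cases}
$$

where $g_\lambda$ is a per-type death probability (in the source experiments
an Annexin-V flow-cytometry estimate — deliberately *not* inferred from the
chamber histograms) and $e_\lambda$ is the unit vector in the parent's own
slot. Row $\lambda$ of the realization matrix $V(t+1)$ sums the $c_\lambda(t)$
independent outcomes, and the next state is the column sum
$c_\lambda(t+1) = \sum_m V_{m\lambda}(t+1)$. An ensemble of $R$ replicates
(default 50) is summarized by per-time, per-type medians with 2.5%/97.5%
quantile bands.

### Parent-survival bookkeeping

Read literally, the update above with the parent *not* retained removes a
surviving quiescent parent from the population: a survivor would contribute
only $u_\lambda^*$, and a quiescent survivor's $u_\lambda^*$ is the zero
vector, contradicting the very definition of quiescence as "live but
non-dividing". The chamber scoring convention (progeny excluding the parent)
and the quiescence analysis both imply that a surviving parent persists. We
therefore default to `parent_retained = TRUE`, adding one cell in the
parent's own slot for every survivor; `literal_equation = TRUE` reproduces
the bare update for comparison. Exactly one of the two semantics is active
per run.

### Counting convention for "cells per dividing parent"

The headline chamber statistics are the quiescent fractions (SKOV3: 12%
ALDH+, 35% ALDH−; primary: 14% / 53%) and the mean number of cells per
dividing single parent (SKOV3: 4.4 ALDH+, 2.2 ALDH−; primary: 2.4 / 1.7).
Whether that mean counts the surviving parent is not self-evident, but the
data decide it: a dividing viable parent plus at least one progeny implies at
least two cells, so a mean of 1.7 *cannot* include the parent.
`mean_cells_per_dividing_parent()` therefore defaults to the
excluding-parent convention (the mean progeny total among dividing records,
the same scale as the chamber histograms' x-axis), with
`include_parent = TRUE` available where total chamber occupancy is wanted.
The `+1` is isolated in that one argument.

## Estimation from chamber tables

`build_offspring_distribution()` tallies progeny vectors of records that are
(i) viable at the endpoint and (ii) from chambers loaded with exactly one
cell; everything else is excluded and the exclusion counts are reported.
Both filters mirror the device's scoring protocol (about 80% of loaded
chambers hold a single cell; dead parents cannot be scored for division
behavior). Frequencies are kept as raw counts, never collapsed to
probabilities, so exact resampling weights survive the JSON round trip.

`transition_support()` reads the state-transition map off the histograms: a
pair (parent *i* → offspring *j*) is supported when some observed vector for
*i* has a positive count of *j*. In the source data ALDH− parents produced
only ALDH− cells, a one-way hierarchy; the structure places no constraint of
its own, so a de-differentiation event (ALDH− → ALDH+) would be incorporated
automatically if data ever contained one.

## The synthetic chamber generator

Because no chamber-level dataset is deposited, the package ships a generator
(`generate_chambers()`, `chamber_preset()`) whose generating law is known
exactly, making estimation and simulation testable end to end. Per parent
type it draws: viability (Bernoulli), quiescence given viable (Bernoulli),
a progeny total for dividing parents from a categorical law on {1..8}, and
an independent type assignment per progeny from an allocation law. Chambers
physically bound how many cells fit, so a bounded support was chosen over an
unbounded family; 8 is an assumption, as the largest observed count is not
printed. The weight on total $k$ is proportional to $r^{k-1}$ with $r$
solved numerically (`progeny_total_probs()`) so the law's mean equals the
printed statistic.

Calibration targets are *only* the printed text statistics — quiescence
fractions 0.12/0.35 (SKOV3) and 0.14/0.53 (primary), dividing means
4.4/2.2 and 2.4/1.7 — since per-bin figure bars are not machine-readable;
the bin-level shape is synthetic. Three further parameters are free, with
defaults chosen once and documented here:

* **Viability**: 0.95 per type for SKOV3 and 0.70 for primary cells,
  consistent with the reported >95% cell-line and >60% primary single-cell
  viability in the device.
* **Death probabilities**: constant 0.05 per type in the scenario presets.
  The source estimates death by flow cytometry but prints no number.
* **ALDH+ allocation split**: an ALDH+ parent's progeny are ALDH+ with
  probability 0.3. This keeps the simulated ALDH+ fraction near its 6%
  baseline over one 72 h step; no printed statistic pins it down.
* **EGFL6 effect**: treatment expanded ALDH− self-renewal, but no numeric
  summary is printed, so the EGFL6 presets scale the ALDH− dividing mean by
  `egfl6_effect` with a *neutral default of 1* — users choose the magnitude.

ALDH− presets allocate zero probability to ALDH+ progeny, preserving the
observed hierarchy exactly.

What passing the round-trip tests shows is therefore internal consistency —
estimator and simulator invert the generator at realistic sample sizes — not
fidelity to features of real chamber data the generator does not emulate:
imaging/scoring error, chamber-to-chamber microenvironment variation,
patient heterogeneity beyond pooling, or correlated progeny types within a
chamber (allocation here is independent per progeny).

## Scenarios and reporting

`scenario_preset()` reproduces the published set-ups: 200,000 SKOV3 cells at
6% ALDH+ (12,000 / 188,000, one 72 h step), 300,000 primary cells at 20%
ALDH+ (60,000 / 240,000, one 120 h step), their EGFL6 counterparts, and an
in-vivo xenograft scenario that follows 200,000 simulated cells and converts
counts to tumor volume at $10^8$ cells/cm³. The in-vivo endpoint is
ambiguous between 21 and 28 days in the source, so the preset defaults to 7
steps of 72 h (21 days) and exposes `horizon`. In-vivo runs are driven by
the same in-vitro chamber statistics — that extrapolation is the method's
own premise, and no in-vivo-specific parameter is invented.

The initial split is computed as `round(total × fraction)` with half-away-
from-zero rounding on the positive compartment and the remainder on the
negative one, so the published round numbers are reproduced and the total is
conserved exactly for any input.

Validation measurements need not fall on multiples of $h$ (e.g. 24 h
time courses against a 120 h step). How sub-step predictions were produced
originally is unstated; `interpolate_trajectory()` makes the package's
stand-in explicit — per-type exponential (log-linear) interpolation between
adjacent steps, falling back to linear at zero counts, with interpolated
rows labeled. It is a reporting convention, not sub-step dynamics.

## Numerical and reproducibility choices

* **Aggregated sampling.** Per-parent outcomes of one type are exchangeable,
  so a step draws one multinomial over the type's distinct outcomes (death
  plus each histogram vector) instead of $c_\lambda(t)$ individual samples —
  the same distribution, but in-vivo populations of tens of millions remain
  tractable. `sample_parent_outcome()` retains the per-cell view and the
  tests check the two agree through the expected-offspring matrix.
* **RNG streams.** One root seed; replicate $r$, type $k$ draws from a
  Mersenne-Twister stream seeded by
  $(\text{seed} + 1000003\,r + 7919\,k) \bmod (2^{31}-1)$. Because each type
  consumes only its own stream, a type that receives no immigration is
  *bit-identical* under changes to other types' initial counts — the
  hierarchy-decoupling property holds exactly, and seed determinism gives
  byte-identical trajectory CSVs.
* **Medians and quantiles.** Medians use the inclusive midpoint convention
  for even $R$; the 2.5%/97.5% bands use the standard interpolating
  (type 7) quantile. Both are stated so reported medians are reproducible.
* **Integer safety.** Counts live in doubles but are validated as integers;
  a step refuses (with an explicit overflow error, never silent promotion)
  any per-type count beyond the exact multinomial sampling range
  ($2^{31}-1$) or totals beyond $2^{53}$.
* **Mean-field oracle.** `mean_offspring_matrix()` gives the analytic
  per-parent expectation $M_{\lambda j} = (1-g_\lambda)(E[u_{\lambda j}] +
  [\lambda = j])$; `mean_field_trajectory()` iterates $c(t+1) = c(t) M$.
  The stochastic engine is tested against it at Monte-Carlo precision
  (3 standard errors), and it doubles as a fast deterministic preview.
* **Problem sizes in the test suite.** Round-trip checks run at 100 / 1,000 /
  10,000 chambers per type, Monte-Carlo oracles at 10,000 replicates of a
  small step and 200,000 per-parent draws — sizes at which sampling error is
  well below the asserted tolerances while the whole suite stays quick.

## Known limitations

* Two states only in the shipped presets; the machinery is $l$-type but the
  published calibration covers ALDH+/ALDH−, which the source itself calls an
  over-simplification.
* Discrete, synchronous generations in units of $h$; no continuous time,
  age structure, spatial structure, or cell–cell interaction.
* The published headline correlations between predicted and observed counts
  (r = 0.98 in vitro, r = 0.92 in vivo) rest on observed counts that were
  never deposited; `compare_predictions()` implements the comparison, but
  those numbers cannot be recomputed here.
* Free parameters above (death rates, ALDH+ allocation, EGFL6 magnitude,
  progeny support bound) shift predictions; they are surfaced as arguments
  rather than hidden constants.
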