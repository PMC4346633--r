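---
title: "fuccitrack: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fuccitrack: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuccitrack)
```

## The problem

When a naive CD8+ T cell meets its antigen it expands clonally through many
rapid divisions. Time-lapse imaging of single cells carrying the dual Fucci
reporter (mKO2-hCdt1 marking G0/G1, mAG-hGeminin marking S/G2/M) shows that
this expansion is not homogeneous: division times are strongly correlated
between siblings, more weakly between cousins and between mother and
daughter, and around the eighth division a subpopulation switches to a slow-
or non-cycling, small, CD62L-high state — the phenotype of central-memory
precursors — and passes that state to its daughters. `fuccitrack` implements
the full analysis chain for such experiments (division trees from track
tables, Fucci phase segmentation, kinship statistics) together with a
branching-process generator that reproduces the statistical structure the
analysis assumes, so that every stage can be tested end to end without any
external data.

## Data model and quality control

The unit of observation is a *well* seeded with a single founder cell.
Tracks arrive as one CSV row per cell (`tree_id`, `well_id`, `cell_id`,
`parent_id`, birth/end times in minutes, fate `DIVIDED`/`DIED`/`CENSORED`).
`build_tree()` validates the binary-tree invariants (one root, two children
per division, child birth equal to parent division within one frame) and
assigns the canonical kinship labels: founder `C1`, first-division cells
`M1`/`M2`, second-division cells `D1`–`D4`. `qc_filter()` applies the
tracking exclusion rules per well: death during imaging, more than one cell
at the start, or a foreign cell entering (an extra root born after time
zero) each drop the entire well.

Two measurement conventions matter everywhere downstream:

* **The founder is never a data point.** Its birth is the start of imaging,
  not a division, so its cycle time is unknowable; `extract_cycle_times()`
  drops it by default and `kinship_pairs(..., include_founder = TRUE)`
  exists only for idealized simulated trees.
* **Measurements cover two division rounds** after the first observed
  cytokinesis: mothers at depth 1 and daughters at depth 2. The
  inheritance table restricts mothers to depth 1 for this reason
  (`mother_depth` argument).

## Division-time model

Cycle times are lognormal per sorted generation, calibrated so the
arithmetic mean and standard deviation at the measured depths equal the
published per-generation summaries (generation 1: 13.4 ± 5.4 h; generation
3: 14.3 ± 4.4 h; generation-8 fast cyclers reuse the generation-3 numbers,
which the source data do not separate). For a target mean $M$ and s.d. $S$
(minutes), $v = \log(1 + S^2/M^2)$ and $m = \log M - v/2$.

On the log scale each cell's time decomposes as

$$\log T \;=\; m_g \;+\; F_\tau \;+\; G_\tau\,(k - k_0) \;+\; B_{\mathrm{div}}
\;+\; \varepsilon,$$

with a per-tree family effect $F$, a per-tree generational drift $G$
evaluated at depth $k$ around $k_0 = 1.5$ (the midpoint of the two measured
rounds), a division shock $B$ drawn once per division and shared by the two
daughters — the stochastic resetting that "randomizes division times equally
for the two daughters" and the sole source of sibling synchrony — and an
individual residual $\varepsilon$. Centering the drift at $k_0$ keeps the
depth-1 and depth-2 marginals exactly at the calibrated lognormal (a drift
proportional to raw depth would inflate the depth-2 variance and break the
printed-summary calibration), while still ordering the relatives: siblings
share $F$, $G$ and $B$; cousins share $F$ and $G$ at equal depth
(covariance $f + g/4$); mother–daughter pairs evaluate the drift on opposite
sides of $k_0$ (covariance $f - g/4$), so cousins always exceed
mother–daughter, the qualitative ordering the tracking data show.

The components are parameterised as *shares* of the generation's total log
variance, constrained by `family + drift/4 + division + individual = 1`.
Defaults (0.2, 0.4, 0.5, 0.2) give log-scale correlations of 0.8
(siblings), 0.3 (cousins) and 0.1 (mother–daughter). These three targets are
a design choice: the source only orders them qualitatively ("very strong"
sibling correlation, cousins above mother–daughter, non-relatives null).
They were fixed once, before the test suite existed, from a pilot that
balanced two stated requirements — a detectable ordering at a few hundred
pairs, and a near-nominal type-I error for the categorical inheritance test
on generation-1 trees.

## The heritable slow state

From `slow_onset_generation` (default 8) onward a two-state Markov switch
runs along the tree: daughters of fast mothers turn SLOW with probability
`p_on` (0.25), daughters of SLOW mothers remain SLOW with probability
`p_stay` (0.8), and a SLOW daughter arrests — never divides in the window —
with probability `p_arrest` (0.35). Non-arrested SLOW cells draw their time
from a slow lognormal with median 30 h (`slow_meanlog = log(1800)`,
`slow_sdlog = 0.35`), placing their upper quartile well past 24 h. Founders
of a sorted generation at or past the onset are SLOW with probability
`p_on`, since a generation-8 sorted population already contains late
dividers; the source defines only the daughter transition, so this founder
rule is ours. The switch is gated by generation because the tracked data
show category inheritance only in generation 8, with generations 1 and 3
consistent with pure resetting. Phenotype is linked deterministically:
SLOW cells are `SMALL`/CD62L `HI`; fast cells are `LARGE` with CD62L `INT`
before the onset generation and `LO` after. The link is an idealization —
the experiments show association, not mechanism.

## Imaging, censoring and the depth cap

Frames are 3–4 min apart and the window spans 66–90 h (both drawn once per
run unless fixed). Cells whose division falls beyond the window are censored
at the window. Simulation additionally caps tree depth (`max_depth`,
default 4); a capped cell is censored *at its own division time*, as if
tracking stopped there. Censoring capped cells at the window instead would
hand every capped fast cell a long division-free span and flood the
analysis with spurious `NO_DIVISION` calls — the one place where a naive
censoring convention visibly corrupts downstream statistics.

## Fucci reporter model and phase segmentation

Within one cycle the generator lays down: a fixed double-negative gap
(`d_dn_min`, 60 min — the early-G1 window between mAG degradation and
mKO2 accumulation), a G1 (mKO2+) segment occupying `g1_frac_fast` (0.25) or
`g1_frac_slow` (0.7) of the remainder, and an mAG+ segment to cytokinesis
whose leading `s_frac` (0.6) counts as S phase for BrdU purposes (the
reporter itself cannot separate S from G2/M). Intensities are
piecewise-linear with a 10-min rise, a 3-min decay (targeted degradation at
the G1/S boundary is fast), a 1000-a.u. plateau, multiplicative lognormal
noise (CV 0.05), and a distinctly higher quiescent mKO2++ level
(2500 a.u.) used by naive-mode founders during their activation lag
(default 24 h, a qualitative placeholder for cycle entry after
stimulation).

`segment_trace()` classifies each frame against inclusive thresholds
(defaults: 20 % of the cycling plateau for positivity; 2000 a.u. for
mKO2++) and smooths by minimum dwell (12 min ≈ 3–4 frames): runs shorter
than the dwell are merged, shortest first, into the longer flanking run.
The smoothing mimics what a human tracker does implicitly; the source does
not quantify it. Intervals tile the trace exactly, so phase durations sum
to the cycle length by construction. With noiseless traces the segmentation
recovers the generator's boundaries within two frames for ≥ 99 % of cells
(the brief double-positive G1/S transition is shorter than the dwell and is
absorbed into the adjacent phase).

## Population readouts

* **Snapshots / cohort kinetics** — live cells at a time point with their
  Fucci state; in naive mode the culture starts 100 % mKO2++ and the mAG+
  fraction overtakes mKO2+ during expansion.
* **CTV dilution** — median intensity halves per division with lognormal
  noise; generations at or past `ctv_floor_generation` (9) are flagged
  indistinguishable from unlabelled background.
* **BrdU pulse** — a cell is labelled iff its own or any ancestor's S phase
  overlapped the pulse interval; fractions are reported within each Fucci
  state at harvest. Labels are cumulative and inherited, so fractions are
  non-decreasing in pulse length, and at short pulses the mAG+ compartment
  leads by construction.
* **Single-cell expansion** — live-cell counts per founder at a horizon
  (48 h default), with a Mann–Whitney utility for comparing simulated count
  distributions only.

## Statistics

`spearman_cor()` uses average ranks with a two-sided t-approximation p, or
an exact full-enumeration p for n ≤ 8 (both are provided because the
original analyses do not state which was used). `permutation_null()`
shuffles the second member of every pair, preserving marginals while
destroying kinship, and reports the add-one empirical p, which can never be
zero.

`inheritance_table()` crosses mother speed categories (fast < 600 min,
medium 600–800, slow > 1000) with daughter categories (plus
`NO_DIVISION` > 30 h). The 800–1000 min band the published categories leave
unnamed is kept as an explicit `INTERMEDIATE` column, reported but excluded
from the test; daughters censored before 30 h without dividing are
`UNCALLABLE` and likewise excluded. The chi-square test (no continuity
correction) assumes independent observations, but dyads within one tree are
clustered by construction — sibling daughters share a division shock —
which makes the all-dyad test anticonservative even when mother and
daughter categories are independent. The default therefore tests one
randomly chosen dyad per tree (seeded) while reporting the complete counts;
`dedupe = "division"` and `"none"` are available for comparison. Expected
counts below 5 raise a flag, not a failure.

The generation-1 cycle-time recovery check in the acceptance suite compares
the simulated mean to its target within two *cluster-robust* standard
errors (from the spread of per-tree means): cells within a family are
correlated, so the naive $s/\sqrt{n}$ would understate the sampling error
of the mean and fail at well above the nominal rate.

## What the generator does not emulate

No spatial geometry or cell–cell contact, no TCR/IL-2 signalling, no in
vivo trafficking, no image formation (tracks and intensity traces are the
interface, not pixels), and death is off by default (dead-cell wells are
excluded upstream in vitro; a per-cycle hazard is exposed for robustness
testing of the QC filter). A green test therefore establishes that the
*pipeline* recovers the stated statistical structure from data that contain
it — not that real imaging data satisfy the model.

## Reproducibility

Every stochastic entry point is seeded; identical config and seed give
byte-identical tracks, traces and ground truth. The command-line interface
(`simulate`, `phases`, `analyze`, `report`) writes a manifest (config hash,
seed, file lists, package version) with every run.
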