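# fuccitrack

Division-tree and Fucci cell-cycle analysis of clonally expanding CD8+
T cells — and a matched branching-process simulator.

## What this is for

Time-lapse imaging of single T cells carrying the dual **Fucci** reporter
(mKO2-hCdt1 marks G0/G1, mAG-hGeminin marks S/G2/M) makes it possible to
follow every division of a clone and ask how division speed is inherited.
Tracked microgrid experiments show three things worth quantifying:

1. division times of generation-1 and generation-3 cells are fast and
   similar (mean ± s.d. 13.4 ± 5.4 h and 14.3 ± 4.4 h);
2. cycle times correlate by kinship — siblings very strongly, cousins more
   than mother–daughter pairs, non-relatives not at all — consistent with a
   stochastic process that resets division times equally for the two
   daughters at each division;
3. around the eighth division a slow/no-division, small, CD62L-high
   (central-memory-precursor-like) state appears and is passed from mother
   to daughter (χ² on speed categories, P < 0.001), while early
   generations show no such category inheritance.

`fuccitrack` implements the full analysis chain for such data — validated
division trees with kinship labels (C1; M1/M2; D1–D4) from track CSVs,
per-well QC exclusion rules, Fucci phase segmentation of fluorescence
traces (including the early-G1 double-negative gap), Spearman kinship
correlations with a permutation null, division-speed category fractions
(fast < 600 min, medium 600–800, slow > 1000, no division > 30 h) and the
mother→daughter inheritance χ² — plus a seeded branching-process generator
that emulates the imaging data (lognormal division times with
family/drift/division-shared variance components, the heritable slow state,
reporter kinetics, CTV dye dilution, BrdU pulses, expansion counts) so the
whole pipeline is testable offline. Details and all modelling assumptions:
`vignettes/fuccitrack-methods.Rmd`.

The model in one line: on the log scale the cycle time of a cell at depth
*k* in tree *τ* is

    log T = m_g + F_τ + G_τ·(k − 1.5) + B_div + ε

with per-tree family effect *F*, per-tree generational drift *G*, a shock
*B* drawn once per division and shared by both daughters (sibling
synchrony), and an individual residual; from generation 8 a two-state
Markov switch (p_on = 0.25, p_stay = 0.8, p_arrest = 0.35) moves cells into
a slow lognormal (median 30 h).

## Worked example

```r
library(fuccitrack)

## generation-1 sorted cohort: cycle times and kinship correlations
cfg1 <- sim_config(n_founders = 300, imaging_window = 20000,
                   max_depth = 3, seed = 42)
sim1 <- simulate_trees(cfg1, traces = FALSE)
cyc  <- do.call(rbind, lapply(sim1$trees, extract_cycle_times))
summarize_cycle_times(cyc$cycle_time, unit = "h")
#> mu = 13.24 h, sigma = 5.27 h, N = 1800
for (rel in c("SIBLING", "COUSIN", "MOTHER_DAUGHTER", "NON_RELATIVE"))
  print(spearman_cor(kinship_pairs(sim1$trees, rel)))
#> Spearman rho = 0.789, P = 2.76e-192, N = 900 (SIBLING)
#> Spearman rho = 0.397, P = 1.63e-46, N = 1200 (COUSIN)
#> Spearman rho = 0.162, P = 1.67e-08, N = 1200 (MOTHER_DAUGHTER)
#> Spearman rho = -0.053, P = 0.115, N = 900 (NON_RELATIVE)

## generation-8 sorted cohort: heritable slow state
cfg8 <- sim_config(generation_offset = 8, n_founders = 1000,
                   imaging_window = 10000, max_depth = 3, seed = 42)
sim8 <- simulate_trees(cfg8, traces = FALSE)
inheritance_table(sim8$trees, seed = 1)
#> <inheritance_table> 3278 dyads (791 tested, dedupe=tree): chi2 = 45.23, df = 6, P = 4.21e-08
#>               daughter
#> mother         FAST MEDIUM INTERMEDIATE SLOW NO_DIVISION
#>   FAST           47     92           70  130          25
#>   MEDIUM         98    165          139  266          70
#>   INTERMEDIATE   89    192          148  214          71
#>   SLOW           83    198          222  698         261
```

Reading the output: the generation-1 cohort reproduces the printed
13.4 ± 5.4 h summary and the kinship ordering
ρ(sib) > ρ(cousin) > ρ(mother–daughter) > ρ(non-rel) ≈ 0. In generation 8,
slow mothers' daughters pile into the SLOW/NO_DIVISION columns and the χ²
rejects independence; the test uses one random dyad per tree (`dedupe`)
because sibling dyads share a division shock by construction and would make
the all-dyad χ² anticonservative. `INTERMEDIATE` is the 800–1000 min band
the published categories leave unnamed — reported, never silently merged.

## Command line

```sh
Rscript inst/cli/fuccitrack simulate --seed 7 --out runs/sim
Rscript inst/cli/fuccitrack phases   --traces runs/sim/traces.csv --out runs/seg
Rscript inst/cli/fuccitrack analyze  --tracks runs/sim/tracks.csv --out runs/res
Rscript inst/cli/fuccitrack report   --results runs/res/results.json
```

Configuration is TOML (`inst/extdata/default_config.toml`); every run
writes a manifest (config hash, seed, inputs/outputs, version).

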