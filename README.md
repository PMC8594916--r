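# ragrowth

Growth-mode inference and rate-limiting apical growth (RAG) kinetics for
single-cell bacterial lineages.

## What this is for

Time-lapse microscopy of growing microcolonies yields per-cell length
trajectories, but deciding whether individual cells elongate linearly,
exponentially, or somewhere in between is notoriously noise-limited:
over one generation the candidate laws differ by only a few percent of
cell length. For apically growing rods (Actinobacteria such as
*Corynebacterium glutamicum*, which insert cell wall at their poles),
the growth law is also a window into which step of wall synthesis is
rate limiting, and into how a population with sloppy septum placement
still keeps a narrow size distribution.

`ragrowth` is aimed at researchers analysing single-cell lineage data
(cell id, parent id, frame times, lengths) and polar fluorescence
profiles. It provides:

* **Wavefront inference** — the package's core. For every time `t` since
  birth, cell length is regressed on birth length across cells that have
  not yet divided. For linear growth `L(t, lb) = a t + lb` (slope 1);
  for exponential growth `L(t, lb) = lb e^(alpha t)` (intercept 0).
  Connecting the fits across times gives average elongation trajectories
  per birth length, corrected for regression dilution caused by
  measurement noise in the birth length
  (`lambda = sigma_lb^2 / (sigma_lb^2 + sigma_noise^2)`), truncated at
  the first division event, differentiated with a local-quadratic
  smoothing filter, and wrapped in 2-sigma bootstrap bands
  (cell-level resampling).
* **The RAG model** — elongation rate proportional to the number of
  polar transglycosylase sites `N(t)` via Michaelis–Menten kinetics
  `dL/dt = alpha C N / (Km + C)`, with recruitment `dN/dt =
  beta (Nmax − N)` (first order) or `dN/dt = beta e^(gamma t)
  (Nmax − N)` (scaffold-accelerated). Closed forms, nonlinear fitting
  with kinetics shared across birth lengths, the saturation-at-birth
  statistic `s0 = v(0)/v_sat`, and mutant scale-factor tests.
* **Population diagnostics** — the adder regression of division length
  on birth length (slope 1 = adder, 0 = sizer) with bootstrap CIs, and
  the exponential-consistency test of `ln(ld/lb)` against generation
  time.
* **Population simulations** — multi-generation growth/division
  simulations contrasting asymptotically linear and exponential growth
  under identical noise, with birth-length distribution summaries.
* **Profile analysis** — background correction of 1D polar fluorescence
  profiles, polar-intensity quantification, demographs, tip-segment
  intensities, proportionality tests, and septum-onset detection.
* **A synthetic colony generator** — seeded, with configurable growth
  law, division control, septum asymmetry and measurement noise, used
  throughout the test suite and usable as a benchmark generator.

## Worked example

Simulate a colony of RAG-growing cells (asymptotic rate 0.04 um/min,
65% saturation at birth, recruitment halving time 8 min), infer its
elongation-rate curves, and fit the kinetic model back:

```r
library(ragrowth)

cfg <- sim_config(growth_mode = "rag")   # defaults: 500 cells, 3-min frames
tab <- simulate_colony(cfg, seed = 42)
tab
#> Lineage table: 500 cells (225 divided, 275 censored), 11310 frames, sampling interval 3 min
#>   birth length: 1.47-3.08 um; generation time: 38.9-89.7 min

adder_regression(tab, n_boot = 500, seed = 1)
#> Adder regression (ld on lb, 225 cells): slope 0.973 [0.897, 1.059] (95% bootstrap CI), intercept 2.342 um

exp_growth_test(tab)
#> Exponential-growth test: 13 generation-time bins, origin-constrained slope alpha = 0.01054 /min

bands <- bootstrap_bands(tab, n_boot = 200, seed = 2)
fit <- fit_rag(bands, variant = "eq2")
fit
#> RAG fit (eq2): beta = 0.07506 /min (halving time 9.2 min), rss = 26.7
#>    curve   v_sat     s0  lb
#> 1      1 0.04013 0.6373 1.9
#> ...
#> 11    11 0.03987 0.6646 2.9
```

The adder slope near 1 says the colony adds a near-constant length per
generation; the recovered asymptotic rates (`v_sat` ≈ 0.040 um/min),
saturations at birth (`s0` ≈ 0.64–0.66 against a generating value of
0.65) and recruitment halving time (9.2 min against a generating value
of 8 min) show the full pipeline — simulation, wavefront averaging, bias
correction, smoothing/differentiation, bootstrap, kinetic fit —
recovering the generating physiology from noisy lengths alone.

A thin command-line front end over the same functions is installed at
`inst/scripts/ragrowth-cli.R` (subcommands `simulate`, `stats`, `infer`,
`fit-rag`, `popsim`, `profiles`).

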