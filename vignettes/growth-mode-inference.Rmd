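---
title: "Inferring single-cell growth modes and rate-limiting apical growth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring single-cell growth modes and rate-limiting apical growth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragrowth)
```

## The problem

Whether a single bacterial cell elongates exponentially, linearly, or in
some intermediate way is surprisingly hard to decide from time-lapse
microscopy. Over one generation a cell roughly doubles, so the candidate
laws differ by only a few percent in length at any moment — less than the
measurement noise of a typical segmentation pipeline. Deciding the growth
law from individual trajectories would require relative errors around a
few percent per frame, which is rarely available.

For apically growing Actinobacteria such as *Corynebacterium glutamicum*
the question matters: cell-wall insertion happens at the poles, and the
growth law constrains which step of wall synthesis is rate limiting and
how the population controls its size distribution. `ragrowth` implements
a conditional-averaging ("wavefront") inference method that extracts
average elongation trajectories and rate curves from noisy lineages, a
mechanistic kinetic model of rate-limiting apical growth (RAG) to fit
those curves, population-level diagnostics, population simulations, and
polar fluorescence-profile quantification. A fully seeded synthetic
colony generator makes every stage testable without microscopy data.

## The wavefront method

The central quantity is the average length surface $L(t, l_b)$: the mean
length at time $t$ since birth of cells born at length $l_b$. Rather than
averaging noisy per-cell curves, the method regresses, at every discrete
sampling time $t$, the observed lengths $L_i(t)$ on the observed birth
lengths $l_{b,i}$ across all cells that have not yet divided. Both pure
laws are linear in $l_b$ —

* linear: $L(t, l_b) = a t + l_b$ (slope 1, intercept $a t$),
* exponential: $L(t, l_b) = l_b e^{\alpha t}$ (slope $e^{\alpha t}$,
  intercept 0),

and empirically the per-time scatter is well described by a line, so the
default fit order is 1 (order 2 is available to verify that the quadratic
coefficient is negligible; on simulated data it is). Connecting the
fitted values for one conditioning $l_b$ across times yields the average
trajectory; the slope/intercept pattern itself is already a growth-law
diagnostic.

**Birth-length bias.** Measurement noise in $l_b$ attenuates every
regression slope by the classical regression-dilution factor
$\lambda = \sigma^2_{l_b}/(\sigma^2_{l_b} + \sigma^2_{\mathrm{noise}})$.
`correct_birth_bias()` divides positive-time slopes by $\lambda$ and
shifts intercepts by $-\hat\beta_t (1-\lambda)\bar l_b$, so the corrected
family is conditioned on the *true* birth length and satisfies
$L(0, l_b) = l_b$. Because the birth length *is* the first recorded
length, the time-0 regression is the exact identity and its residual is
zero; the noise variance is therefore estimated from the residuals of the
earliest positive-time fits by solving
$R_t^2 = \sigma_n^2 (1 + s_t^2/\lambda)$, or supplied directly when
known. Biological growth variability inflates those residuals, so the
estimate is an upper bound on the noise; on simulated colonies with
deterministic growth the recovered $\lambda$ matches the analytic factor
to well under 1%. A single global $\lambda$ is used: within the valid
time range nearly all cells are still present, so the conditioning
distribution barely changes with $t$.

**Division cutoff.** Once cells start dividing, the per-time fits
condition on survivors, and — because at fixed birth length
faster-growing cells divide earlier — the surviving subpopulation
under-represents fast growers and biases rates low. Trajectories are
therefore computed everywhere but masked beyond the minimum observed
generation time (`division_cutoff()`). Slow-divider subpopulations can be
analysed past this point simply by filtering the input table and rerunning
the pipeline; no special casing is needed.

**Smoothing and differentiation.** Elongation-rate curves are the time
derivative of the average trajectories. We use a local-quadratic
least-squares (Savitzky–Golay) derivative filter over
`smoothing_window = 5` frames (15 min at 3-min sampling). A plain
centered moving average followed by finite differences was considered
and rejected: its one-sided differences at the mask edges carry a bias
of order $h \cdot L''$, which at the strongly curved start of a RAG
trajectory reaches several percent and noticeably degrades the coverage
of bootstrap bands; the local-quadratic filter is exact for linear
trajectories, second-order accurate elsewhere, and uses shifted (but
still quadratic) windows at the edges. The window is a tunable
trade-off: wider windows reduce variance but blur the early-time rise of
the rate curve.

**Uncertainty.** `bootstrap_bands()` resamples whole cells with
replacement — preserving within-cell correlation — and reruns the entire
pipeline per replicate; bands are the point estimate $\pm 2$ bootstrap
standard deviations per $(t, l_b)$. Three fixed choices keep replicates
comparable: the time grid and division cutoff of the full-data fit are
reused, the estimated noise standard deviation is held fixed (only the
birth-length variance is recomputed per replicate), and replicates with
fewer than 3 distinct cells at some time contribute no value there. In a
calibration experiment (100 simulated RAG colonies of 200 cells,
`n_boot = 100`), the 2-sigma bands cover the true rate at slightly over
90% of grid points; the residual undercoverage sits at the mask edges
where smoothing bias is largest.

**Reverse time.** `reverse_time_family()` applies the same construction
aligned at division, regressing interpolated lengths at offsets
$\tau = t - t_d \le 0$ on division length; offsets beyond the shortest
generation time are masked for the same conditioning reason as above.

## The RAG model

Polar wall synthesis is modelled as transglycosylases (TG) incorporating
the lipid-linked precursor (Lipid-II, concentration $C$) with
Michaelis–Menten kinetics, with elongation proportional to wall
production:
$$\frac{dL}{dt} = \alpha\,\frac{C N(t)}{K_m + C},$$
where $N(t)$ is the number of polar TG sites. Assuming $C$ constant or
$C \gg K_m$, the rate is proportional to $N(t)$ alone, so rate curves are
parameterised by the asymptotic rate $v_{sat}$ and the relative
saturation at birth $s_0 = v(0)/v_{sat}$ — relative quantities; absolute
site numbers are never identified. Two recruitment kinetics are
implemented:

* first order (`gamma = 0`): $dN/dt = \beta (N_{max} - N)$, giving
  $v(t) = v_{sat} - v_{sat}(1 - s_0) e^{-\beta t}$; the gap to
  saturation halves every $\ln(2)/\beta$ minutes, which makes the onset
  time of the linear regime insensitive to $N(0)$ and $N_{max}$;
* self-accelerated (`gamma > 0`): recruitment proportional to an
  exponentially growing polar scaffold cluster (DivIVA-like),
  $dN/dt = \beta e^{\gamma t}(N_{max} - N)$, giving
  $v(t) = v_{sat} - v_{sat}(1-s_0)\exp(-(\beta/\gamma)(e^{\gamma t}-1))$,
  which reproduces a sharper inflection. The first form is the
  $\gamma \to 0$ limit of the second (implemented with `expm1` so the
  limit is numerically exact).

Lengths use the closed form for $\gamma = 0$ and adaptive quadrature
(absolute tolerance $10^{-9}$ um) otherwise; both agree with an
independent ODE integration to better than $10^{-8}$ relative error.

**Fitting.** `fit_rag()` fits a family of rate curves with the
recruitment kinetics ($\beta$, and $\gamma$ for the accelerated variant)
shared across conditioning birth lengths and $(v_{sat}, s_0)$ free per
curve — the most parsimonious scheme consistent with the observed
robustness of the saturation timing across birth lengths. For fixed
kinetics the model is linear in $(v_{sat}, v_{sat}(1-s_0))$, so per-curve
parameters are profiled out by weighted linear least squares and only the
shared kinetics are searched: a log-spaced grid over
$\beta \in [10^{-3}, 1]\,\mathrm{min}^{-1}$ refined by one-dimensional
optimisation (`eq2`), or Nelder–Mead from multiple starts including the
`eq2` optimum (`eq3`, which therefore never fits worse than `eq2`).
Bootstrap band widths, when present, enter as $1/\mathrm{sd}^2$ weights.
On noise-free curves parameters are recovered to well under 1%; with 5%
multiplicative noise the saturation at birth is recovered within ±5
percentage points in well over 90% of replicates.

## The synthetic colony generator

`simulate_colony()` emulates the relevant features of chamber-microfluidic
time-lapse data: 3-min frames over several generations, founder birth
lengths from a truncated Gaussian (mean 2.3 um, sd 0.2, truncated to
[1.9, 2.9] um — matching the conditioning grid of the inference), a wide
generation-time spread, septum-placement asymmetry (truncated Gaussian
fraction, mean 0.5, sd 0.05, kept inside [0.2, 0.8]), additive Gaussian
measurement noise on recorded lengths (default sd 0.05 um, a few percent
of a typical cell), and per-cell growth-rate variability (multiplier CV
0.15 applied to the rate parameter). True lengths drive the dynamics;
noise touches only the recorded values. Division control is pluggable
(adder, sizer, timer, near-adder with configurable slope), and division
targets are met exactly: each divided cell's final record is the exact
division event, so identities like $l_d - l_b = \Delta$ for a noise-free
adder hold exactly on the recorded series, at the cost of a final
sampling interval that may be shorter than the frame interval (the
validator knows about this). Daughters receive complementary fractions of
the mother's true division length (exact conservation) and restart their
recruitment state at birth (new pole unsaturated, old pole saturated),
which is how the RAG growth law is inherited.

What the generator does *not* emulate: spatial colony structure and
crowding, segmentation artefacts with heavy-tailed errors, pole-age
tracking across more than one generation, and correlated mother–daughter
growth rates. Passing recovery tests on this generator therefore shows
that the inference is unbiased and well calibrated under idealised
noise, not that it is robust to every real-data pathology.

## Population simulations

`simulate_population()` contrasts birth-length homeostasis under
asymptotically linear (RAG) and hypothetical exponential growth with
identical division/timing noise: division length is
$l_d = l_b e^{\alpha(t_t + \Delta t)} + \Delta l$ (exponential) or
$l_d = \mathrm{rag\_length}(t_t + \Delta t, l_b) + \Delta l$ (RAG), with
a target time $t_t$, time-additive noise $\Delta t$, size-additive noise
$\Delta l$, and truncated-Gaussian septum fractions. Defaults ($t_t =
60$ min, $\alpha = \ln 2/t_t$, $\Delta t$ sd 12 min, $\Delta l$ sd
0.15 um, RAG $v_{sat} = 0.04$, $s_0 = 0.65$, $\beta = \ln 2/8$; 10
generations, 3 discarded as burn-in) are chosen once so that the
noise-free stationary birth length is about 2.3 um in both modes and the
generation-time spread is wide.

The qualitative contrast is robust: with a fixed target time the
exponential mode has no size feedback (a neutral multiplicative random
walk), so its birth-length distribution is far wider, with more mass in
the upper tail, whereas the RAG mode is adder-like and strongly
homeostatic. One quantitative expectation is *not* reproduced under this
model: rescaling all noise amplitudes leaves the ratio of the two CVs
nearly invariant (both widths scale linearly in the small-noise regime),
so reducing noise threefold narrows both distributions but does not
bring their CVs within 25% of each other here. Making the two modes
comparably narrow at reduced noise would require additional structure —
for example fewer accumulating generations or birth-length-dependent
asymptotic rates — that the present division model does not include.

## Profile analysis

Polar fluorescence profiles (for example of a fluorescent D-amino-acid
stain of nascent wall material) are background-corrected by subtracting
the minimum over the central 30% of the cell, where non-dividing cells
consistently show the cytoplasmic level; a mid-cell value far above the
windowed minimum flags a likely septal peak. Note that with additive
intensity noise the minimum is biased low, so corrected intensities gain
a small positive offset proportional to the noise sd — the
proportionality between polar intensity and elongation rate is exact in
the noise-free limit and acquires this intercept otherwise. Polar
intensities are means within 0.77 um of each tip (the width is a
parameter; results are insensitive to it, and 0.78 um is an equally
defensible choice), and `moving_average_by_length()` presents per-cell
quantities against cell length with a ±0.7 um window. `septum_onset()`
declares the onset of septum formation at the first sustained (two-frame)
excursion of the mid-cell signal above baseline mean + 3 sd; the
threshold and baseline window are parameters because "sharp increase" is
not otherwise operationalised.

## Numerical choices and degenerate inputs

* Quadrature: `integrate()` with absolute tolerance $10^{-9}$ um;
  failures raise an error rather than returning a partial result.
* Multi-start kinetics search: 64-point log-spaced $\beta$ grid (`eq2`);
  8x4 starts plus the `eq2` optimum (`eq3`). Per-curve constraints
  ($v_{sat} > 0$, $0 < s_0 \le 1$) are enforced by clipping the profiled
  linear solution.
* Attenuation: an estimated noise variance at or above the observed
  birth-length variance is a degenerate correction and raises an error.
* Validation tolerances: daughter-length conservation is exact on true
  lengths; for observed tables the validator allows
  $5\sqrt{3}\,\sigma_{\mathrm{noise}}$ when the metadata records a
  measurement-noise sd.
* Truncated draws (birth lengths, septum fractions, growth multipliers,
  division targets) use rejection sampling with a clamped fallback, and
  division targets are forced above the birth length.
* Ties and empty windows: moving averages drop query points with empty
  windows; wavefront times with fewer than 3 cells or degenerate
  birth-length spread are dropped.

## Problem sizes

The test suite and validation scripts use colonies of 200–2000 cells
(500 for growth-mode recovery, matching the scale of a typical chamber
experiment), 50-replicate recovery experiments for the saturation
parameters, 100-replicate calibration for the bootstrap bands, and
population simulations of up to 20000 cells over 10 generations. These
sizes give Monte-Carlo errors comfortably below the tolerances they are
tested against.

## Known limitations

* Single trajectories are never classified; the method infers population
  averages conditioned on birth (or division) length by design.
* The attenuation estimate absorbs biological variability into the noise
  term and therefore slightly overcorrects when growth-rate variability
  is large; supplying a known noise sd avoids this.
* Saturation values are relative; $\alpha$, $K_m$, $C$ and absolute site
  counts are not identifiable from rate curves alone.
* The bootstrap reuses the full-data time grid and cutoff, so replicate
  variation in the cutoff itself is not propagated.
* The population simulation's exponential mode is a pure timer; division
  strategies with partial size feedback would interpolate between the
  two contrasted extremes.
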