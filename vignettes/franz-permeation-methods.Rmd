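---
title: "Methods: Franz-cell permeation kinetics, simulation, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Franz-cell permeation kinetics, simulation, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(franzperm)
```

## The measurement model

A Franz diffusion cell exposes a membrane of area $A$ (cm²) to a donor
formulation above and a stirred receptor chamber of volume $V_r$ (mL)
below. At each scheduled time $t_n$ a sample of volume $V_s$ is withdrawn
from the receptor and replaced with fresh buffer, and its drug
concentration $c_n$ (µg/mL) is assayed. Because each withdrawal removes
drug, the cumulative amount permeated per unit area must be reconstructed
with the dilution correction

$$Q_n = \frac{c_n V_r + V_s \sum_{i<n} c_i}{A} \quad (\mu g\,cm^{-2}).$$

`cumulative_amount()` implements exactly this; it is the algebraic
inverse of the simulator's sampling bookkeeping, which is what the
machine-precision round-trip tests establish.

## Steady-state kinetics

For a homogeneous membrane (thickness $h$, diffusivity $D$, partition
coefficient $K$) under infinite dose and perfect sink, the cumulative
amount follows the classical diffusion-lag series

$$Q(t) = K h C \left[ \frac{Dt}{h^2} - \frac16 - \frac{2}{\pi^2}
\sum_{n\ge1} \frac{(-1)^n}{n^2} e^{-D n^2 \pi^2 t / h^2} \right],$$

whose late-time asymptote is the straight line with slope
$J_{ss} = K D C / h = k_p C$ and x-intercept $L_T = h^2 / 6D$. The
experimental estimates are obtained, as is standard in IVPT practice, by
ordinary least squares of $Q$ on $t$ over the linear portion:
$J_{ss}$ is the slope, $L_T = -\text{intercept}/\text{slope}$, and
$K_p = J_{ss}/C_{donor}$.

**Window selection.** Which points constitute "the linear portion" is
rarely stated in experimental reports, so the choice is made explicit
and pluggable here. The default strategy enumerates every contiguous
window of at least 4 points, keeps those with positive slope, and selects
the one maximizing $r^2$, breaking ties by longer window and then
earlier start. With at most 8–12 timepoints the exhaustive search is
trivially affordable and the tests verify it against an independent
`lm()`-based search. The selected window is recorded in every fit. A
terminal-window strategy (`"last_points"`) is available as an
alternative.

**Donor concentration.** $C_{donor} = 50{,}000\ \mu g/cm^3$ throughout:
all creams are formulated at 5% w/w active equivalents and unit density
is assumed. This single value reproduces the free-acid worked example
($36.98 / 50000 = 0.74\times10^{-3}$ cm/h) exactly; a few published
permeability values differ from this arithmetic by up to ~1% in the last
digit, which the pipeline surfaces as annotations rather than asserting
away.

**Negative lag times** can arise on noisy replicates when the fitted
line crosses the origin to the left. They are reported as-is with a
warning — clipping would hide a diagnostic for a mis-selected window or
an unusually noisy cell.

**Aggregation.** Fits are per cell and then aggregated as arithmetic
mean ± sample SD (n−1), matching the triplicate mean ± SD convention of
permeation studies. Fitting the mean profile instead is possible by
averaging first, but is deliberately not the default: per-cell fits
propagate between-cell variability into the reported SDs.

## The synthetic-data generator

No raw concentration series are publicly deposited for the motivating
study, so the generator *is* the data source for every recovery test.
Its stated world:

* **Kinetic panel.** One $(k_p, L_T)$ pair per compound × membrane,
  taken directly from the published summary kinetics of the ten
  ibuprofen/valine-ester formulations (skin
  $k_p \approx 0.47$–$1.12\times10^{-3}$ cm/h, Strat-M
  $0.64$–$4.09\times10^{-3}$ cm/h, lag times 0.55–2.22 h). Thickness is
  fixed per membrane — 0.05 cm for dermatomed skin, 0.03 cm for Strat-M
  (its nominal 300 µm) — and $D$, $K$ are back-solved. This makes the
  simulated summary tables land, by construction, in the observed ranges.
* **Schedule.** Sampling at 0.5, 1, 2, 3, 4, 5, 8, 24 h: the source
  protocol says only "predefined times", so a schedule dense around the
  3–5 h rate peak was fixed once; it is configurable.
* **Noise.** Multiplicative Gaussian on each measured concentration,
  truncated at zero, default CV 5% — chosen because reported SDs are
  roughly proportional to means, as a fixed-CV assay error produces.
* **Sampling bookkeeping.** The withdrawal sums use the *measured*
  concentrations, so measurement noise enters each cumulative point only
  once and the dilution correction inverts the generative model exactly.
  (Physically the withdrawn mass tracks the true concentration; the
  difference is second order in the noise and irrelevant at 5% CV.)
* **Simplifications.** Infinite dose (max. observed permeation is a few
  percent of the ~50 mg applied dose), perfect sink (receptor stays far
  below donor), no membrane heterogeneity, binding, or vehicle
  evaporation. Membrane accumulation is treated as a separate assay
  input, not an emergent property of the diffusion model.

Consequently a green recovery test establishes that the *pipeline*
correctly inverts this idealized world — not that real skin data meet
the same error bounds. Real tissue adds inter-donor variability,
non-Fickian barrier behavior, and assay artifacts that are explicitly
out of scope.

## Numerical choices

* The diffusion series is truncated when the next term changes $Q$ by
  less than $10^{-10} K h C$; the alternating, eventually-monotone terms
  make the first omitted term a valid error bound. Small negative
  truncation residues near $t=0$ are clamped to zero.
* The test-suite physics oracle is a central-difference semi-discrete
  solver (≥ 200 spatial nodes) propagated *exactly* in time through its
  eigenmodes and Richardson-extrapolated from $n_x$ and $2n_x$; its
  agreement with the series is a genuine two-route check because it
  never uses the Fourier solution.
* Tukey HSD adjusted p-values are computed from the studentized range
  distribution with the Tukey–Kramer standard error (verified against
  `TukeyHSD()` in the tests); the compact letter display uses the
  insert-and-absorb construction, letters ordered 'a', 'b', … by
  ascending group mean so 'a' always marks the slowest group. A
  zero-MSE degenerate input falls back to p = 1 (equal means) or p = 0.
* Clustering standardizes each feature column (zero-variance columns are
  dropped with a warning), uses Euclidean distance with `ward.D2` (the
  true Ward criterion on distances), defaults to $k = 3$, and relabels
  clusters by descending terminal cumulative mass so cluster 1 is always
  the fastest-permeating group. The linkage/distance were open choices —
  no method is named in the motivating report — and are configurable.
* Comparisons against the free-acid control reuse the Tukey-adjusted
  pairwise p-values (a Dunnett-style reading, slightly conservative);
  this is an approximation and is documented as such.

## Dose equivalence

Formulations are weighed so each cream delivers the same active dose:
$m_{active} = m_{salt} \cdot M_{active}/M_{pair}$. Molar masses are
registry data, never recomputed from atomic composition — published
tables for these salts disagree in the last digit (and in one case,
the hexyl ester, by two g/mol), so the registry carries a dosing value
and a display value separately. One printed batch mass (the propyl
ester's 0.0896 g) implies 50.57 mg of active, 1.1% above the 50 mg
design dose; the package reports what the arithmetic gives.

## Known limitations

* Steady-state estimates assume the 24 h point is still in the linear
  regime; with strong donor depletion (not modeled) late points would
  flatten and bias $J_{ss}$ low.
* The lag time is an extrapolated x-intercept and inherits amplified
  noise; its recovery tolerance (median relative error < 20% at 5% CV)
  is intrinsically looser than the flux's (< 5%).
* The cluster memberships of real compounds are an experimental outcome;
  the simulator reproduces them qualitatively because its panel encodes
  the same kinetics, and the package makes no claim beyond that.
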