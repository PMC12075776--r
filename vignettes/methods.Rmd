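---
title: "Methods: instantaneous rates from sparse growth curves, capsule morphometrics, and recruitment ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instantaneous rates from sparse growth curves, capsule morphometrics, and recruitment ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsegrowth)
```

# Why instantaneous rates

Oligotrophic marine isolates grow slowly and are counted by flow cytometry
at irregular, sparse intervals. Whole-curve parametric fits (logistic,
Gompertz, Baranyi) are fragile on 8–15 points with unknown lag and
saturation behaviour. `sparsegrowth` instead estimates the *instantaneous*
doubling rate locally and lets the data delimit the exponential phase.

## The sliding-window chain

For a curve of $n$ strictly increasing times $t_i$ (days) and densities
$N_i > 0$ (cells/ml):

1. Every consecutive triplet ($n - 2$ windows, stride 1) gets an OLS fit of
   $\log_2 N$ on $t$. The slope $b$ is the instantaneous doubling rate over
   the window; with one residual degree of freedom its standard error is
   $\mathrm{SE}(b) = \sqrt{\mathrm{SSE} / \sum_i (t_i - \bar t)^2}$.
   Stride 1 is used because it maximizes the use of sparse data and makes
   each interior time point contribute to several estimates; the "standard
   deviation" attached to a window is the OLS slope standard error, the
   only uncertainty a 3-point regression natively provides. Windows other
   than 3 points are rejected: wider windows smooth across phase
   transitions that sparse curves cannot localize.
2. $\{b - \mathrm{SE},\, b,\, b + \mathrm{SE}\} \times
   \{t_\mathrm{start}, t_\mathrm{mid}, t_\mathrm{end}\}$ yields nine
   candidate rates per window.
3. The median of all candidates pooled at each unique time is the rate
   series $r(t)$. Candidates are pooled plainly — not deduplicated or
   weighted by window — so the median is invariant to candidate ordering
   and batch splitting. Negative rates (death phase) are retained here;
   only the phase selection excludes them.
4. A decreasing four-parameter logistic
   $r(t) = r_{low} + (r_{high} - r_{low})\,/\,(1 + e^{(t - t_{inflect})/\tau})$
   is fitted to $r(t)$ by bounded Levenberg–Marquardt (`minpack.lm::nlsLM`,
   $\tau \ge 10^{-8}$, 200 iterations). The functional form is a design
   choice: among decreasing sigmoids it is the simplest with an explicit
   inflection parameter. Initials are $r_{high} = \max r$,
   $r_{low} = \min r$, $t_{inflect}$ at the span midpoint,
   $\tau = \mathrm{span}/8$, followed by up to five restarts from a fixed
   table of multiplicative perturbations of those initials — deterministic
   by construction, so no RNG state is involved. The best
   residual-sum-of-squares solution is accepted only if the optimizer
   succeeded, $t_{inflect}$ lies within the observed span,
   $r_{high} > r_{low}$ and $\tau > 0$; series with fewer than four
   distinct times, flat series, and rising series are declared
   non-converged without error.
5. Exponential phase: all times strictly before $t_{inflect}$ when the fit
   converged (falling through to the fallback if no point precedes it);
   otherwise the three largest-$|r|$ entries (all of them if fewer than
   three), with ties on $|r|$ broken toward the earlier time and output
   ordered by ascending time. The magnitude criterion means a fast death
   phase can be selected on a declining curve — intended behaviour, since
   the fallback is a last resort for curves without a clear plateau
   structure.

## Condition summaries and envelopes

`summarize_condition()` pools exponential-phase rates across replicates.
The representative rate is the pooled **median**; the SD, mean and range
are all reported because published "center ± spread" conventions are often
left unstated. A condition *grows* when the representative rate is at
least `rate_floor` (default 0.1 doublings/day) **and** some replicate's
density increased at least `fold_floor`-fold (default 4). These floors are
package choices, config-exposed: a rate floor alone flags noise-level
slopes on flat curves, and the fold floor separates sustained growth from
transient blips. `growth_envelope()` orders summaries along one condition
variable, reports the range of growth-positive values (the permissive
range), and the maximum representative rate with its condition. With no
growth-positive condition it returns a flagged empty envelope rather than
raising.

# Capsule morphometrics

Cells are modelled as capsules (spherocylinders): a cylinder of height $h$
capped by two hemispheres of radius $r$, total length $l = h + 2r$. A
segmented 2-D projection is a stadium of area
$S = 2r(l - 2r) + \pi r^2$, inverted as $l = (S - \pi r^2)/(2r) + 2r$,
which requires $S \ge \pi r^2$. Volume and surface follow as
$V = \pi r^2 h + \tfrac43 \pi r^3$ and $SA = 2\pi r h + 4 \pi r^2$. Axis
curvature is ignored: a curved tube of the same axis length has identical
volume, and no curvature is measurable from $S$ and $r$ alone.

Pleomorphic cells are measured with several radii against one shared area;
each radius produces its own $(l, h, SA, V)$ record. Radii violating
$S \ge \pi r^2$ (a bulge wider than the projection allows) are flagged
invalid and dropped from the per-cell mean/median rather than failing the
cell; only an all-invalid cell errors. Population summaries take one
representative value per cell — median by default, matching median bars on
violin plots, with mean available — and report mean/median/SD plus a long
table ready for violin plotting. Note that because $V$ is nonlinear in
$(l, r)$, the capsule formula evaluated at population-mean dimensions is a
different quantity from the population-mean volume; the package never
conflates the two.

# Media calculators

Exact, linear, no tolerances: salinity (ppt) $= 1.80655 \times$ chlorinity
(ppt), computed on the base salts (an optional additive chlorinity term
defaults to 0 because nutrient-stock chloride is negligible); two-batch
mixing fractions $f = (\mathrm{target} - \mathrm{lo}) /
(\mathrm{hi} - \mathrm{lo})$ with exact reconstruction; total carbon
$\sum c_i k_i$ for concentrations $c_i$ (µM) and per-molecule carbon
counts $k_i$, with `mix_for_target()` as its exact inverse. Carbon counts
are always caller-supplied (a small reference vector `carbon_atoms` covers
methionine 5, glycine 2, pyruvate 3, asparagine 4) — never parsed from
compound names, to avoid silent chemistry errors.

# Recruitment ecology

* **RPKM**: $\mathrm{counts}/(\mathrm{genome\ length}/10^3)/
  (\mathrm{recruited\ bp}/10^6)$, zero exactly where counts are zero. The
  denominator is interpreted as the total base pairs of reads mapped to
  any reference in the competitive recruitment (pass total sample bp
  instead if that convention is wanted — the text definitions in
  circulation are ambiguous).
* **Subcluster sums**: exact per-sample sums over member genomes;
  unassigned genomes are excluded with a warning so partial membership
  maps do not fail whole tables.
* **ANI clustering**: asymmetric matrices are symmetrized by the pair mean
  (minimum available by flag), genomes are linked where symmetrized ANI
  meets the threshold (default 95 %, the conventional species boundary),
  and clusters are connected components — single linkage, mirroring how
  species boundaries are applied in practice; no centroid re-assignment.
  The threshold constrains *edges*: within-cluster minimum ANI is reported
  as a statistic and may fall below it.
* **Quality**: completeness $- 5 \times$ contamination, the usual
  dereplication ranking.
* **Environment correlation**: Spearman's $\rho$ per subcluster against a
  per-sample variable, pairwise-complete, requiring at least three
  complete pairs; constant inputs leave $\rho$ undefined (flagged, not
  raised).

# The synthetic-data generators

The generators exist so that every analysis stage has a forward model that
it exactly inverts in the zero-noise limit.

* **Growth curves**: lag (density held at $N_0$), then logistic
  $N(t) = K/(1 + (K/N_0 - 1)e^{-\mu \ln 2 (t - \mathrm{lag})})$ (Gompertz
  by flag; logistic is the default because the estimator only assumes
  log-linear early growth). Observation noise is multiplicative lognormal
  with coefficient of variation `noise_cv`, the natural error scaling for
  flow-cytometry counts; the log-scale sd is $\sqrt{\ln(1 + cv^2)}$, so
  $E[N_{obs}] = N(t)\,e^{\sigma^2/2}$.
* **Condition envelopes**: the true rate responds to temperature (or a
  salinity analogue) through Rosso's cardinal model (CTMI), chosen over a
  quadratic for its asymmetric envelopes; it is zero at and outside
  $(x_{min}, x_{max})$. The CTMI rational form is only bounded by
  $\mu_{opt}$ when $x_{opt} \ge (x_{min} + x_{max})/2$ — the usual
  slow-rise/sharp-fall microbial geometry — and other geometries are
  rejected outright rather than silently producing super-optimal rates.
* **Cell populations**: lognormal lengths and radii (resampled until
  $l \ge 2r$), exact stadium areas, and per-cell noisy radius readings.
* **Recruitment**: per-genome log abundance linear in an environmental
  variable plus lognormal noise, normalized per sample; counts are the
  rounded share of the per-sample read budget and `recruited_bp` is
  defined as counts × read length, keeping the table exactly
  self-consistent.

All generators restore the caller's RNG state and are byte-identical per
seed.

What the generators emulate: sparse/irregular sampling, lag–exponential–
stationary structure, multiplicative count noise, pleomorphic size
scatter, environment-driven abundance gradients. What they do not:
death-phase kinetics, non-lognormal outliers, segmentation artefacts,
compositional coupling between many taxa, or read-level mapping biases.
Passing recovery tests therefore demonstrates correctness of the inference
chain under its own assumptions, not robustness to every failure mode of
real data.

## Verification scales

The suite verifies window OLS against `stats::lm` at $10^{-12}$, capsule
volume/surface against numeric solid/surface-of-revolution integration at
$10^{-6}$ relative, stadium inversion round-trips at $10^{-10}$, ANI
clustering against a brute-force union–find on matrices up to 20 genomes,
and parameter recovery on 200 seeded logistic simulations (true $\mu$ =
1.5 doublings/day, 10 samples over 6 days, $N_0 = 10^4$, $K = 10^7$
cells/ml, 0.5 d lag, 1 % count noise — sizes chosen to represent one
realistic bench experiment per seed while keeping the whole suite fast),
requiring the representative rate within 5 % of truth in at least 95 % of
seeds. Envelope recovery uses a 4 °C grid over a (14, 21, 27) °C cardinal
response and must localize both cardinal bounds within one grid step.

# Known limitations

* The exponential-phase boundary is an *estimate*; strict-inequality
  selection at $t < t_{inflect}$ can drop a point sitting exactly on a
  slow inflection.
* Three-point windows give noisy SEs; the candidate/median construction
  compensates but very noisy curves (cv well above a few percent) widen
  the recovered-rate distribution.
* The capsule inversion assumes the segmented area is a true orthogonal
  projection; tilted or partially out-of-focus cells bias lengths
  upward.
* Single-linkage ANI clustering can chain clusters through borderline
  pairs; the reported within/between statistics make such chaining
  visible but the assignment itself does not prevent it.
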