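---
title: "Methods: monolayer-vs-spheroid screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monolayer-vs-spheroid screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroscreen)
```

## Scope and scientific setting

High-throughput anti-cancer screens are usually run in monolayer (2D)
culture, yet drugs that look potent on a plastic dish often fail against
the three-dimensional architecture of a tumor. Screening the same
compounds against spheroids — 3D aggregates grown from the same cell
lines — exposes compounds whose activity depends on the culture format.
This package implements the complete analysis for such a two-stage
screen in four anaplastic thyroid carcinoma (ATC) lines (THJ-11T,
THJ-16T, THJ-21T, THJ-29T): a broad AUC-based primary screen, a
curation step, and a 2D/3D confirmation screen whose differential
statistic (deltaAA) feeds a majority-of-lines elimination rule.

Because the real assay data cannot ship with the code, every stage runs
against a synthetic screen generator with planted ground truth. The
generator is not a convenience mock: it is first-class, tested code, and
the recovery of its planted structure is the package's main evidence of
correctness.

## The viability statistic

Each well is imaged repeatedly after treatment; segmented nuclei are
classified live or dead by dead-cell-stain overlap. With live count
$L_t$ and dead count $D_t$, the dead fraction is $f_t = D_t/(L_t+D_t)$,
and the well-level response is

$$V = 1 - \max\{\, f_t : 0 \le t \le w \,\}, \qquad w = 72\ \text{h by default}.$$

Taking the *maximum* dead fraction over the window makes the statistic
sensitive to transient killing that regrowth would otherwise mask.
Choices worth stating explicitly:

* Timepoints with $L_t + D_t = 0$ carry no information and are skipped
  (never treated as $f=0$ or $f=1$).
* The baseline $t=0$ point participates in the maximum; by construction
  its dead fraction is near zero, so this is benign.
* The statistic is scale-invariant: multiplying all counts by a constant
  leaves $V$ unchanged, so it is robust to segmentation gain.
* Enlarging the window can only lower (or preserve) $V$ — a maximum over
  a superset.

The *primary* screen uses a different, single-endpoint normalization:
viable (stain-negative) count at 72 h divided by the mean viable count of
same-plate vehicle controls. That ratio may exceed 1 (growth beyond
control); no dead-fraction information is used. Both statistics feed the
same dose–response machinery. Control (DMSO) normalization of the
time-resolved statistic is deliberately *not* applied by default: the
dead-fraction form is already internally normalized per well.

## Dose–response model and activity metrics

Viability versus concentration is modelled with the four-parameter
log-logistic (4PL)

$$E(c) = E_{inf} + \frac{E_0 - E_{inf}}{1 + (c/EC_{50})^{h}},$$

fit by bounded Levenberg–Marquardt least squares in $\log_{10} c$ space
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-12`, 200 iterations).
Initialization: $E_0 \leftarrow \max y$, $E_{inf} \leftarrow \min y$,
$EC_{50}$ at the concentration closest to the half-range crossing,
$h \leftarrow 1$. Default bounds: $E_0, E_{inf} \in [0, 1.2]$,
$h \in [0.1, 10]$, $EC_{50}$ within two decades of the tested range.

The top asymptote is bounded at 1.2 rather than left free: responses are
normalized viability, so values above ~1 reflect replicate noise or
growth beyond control, not pharmacology. On shallow noisy curves an
unconstrained top trades off against the midpoint (the optimizer can
represent the same data as a taller, flatter curve shifted left), which
measurably degrades $EC_{50}$ recovery; the bound encodes the assay's
normalization as a prior.

A curve is reported *unfit* (`converged = FALSE`) when its response
range is below 0.1 (a flat curve supplies no information about any
parameter), when the optimizer fails, or when the fitted bottom exceeds
the fitted top (a rising "inhibition" curve). Unfit curves are the grey
cells of a screening heatmap; they still receive fit-independent metrics.

Two area metrics are computed directly from the observed points over
$x = \log_{10} c$, normalized by the tested span:

* $AUC = \int y\, dx / \mathrm{span}$ — 1 for a flat fully-viable curve,
  lower is more active; the primary screen's ranking statistic.
* $AA_{obs} = \int \max(0, b - y)\, dx / \mathrm{span}$ with baseline
  $b = 1$ — 0 for no activity, higher is more active, and independent of
  any fitted model.

Span normalization makes the two comparable across the 5-point primary
and 10-point confirmation series and yields the exact complement
$AA_{obs} + AUC = 1$ whenever all responses lie in $[0,1]$. Both report
the relative EC50 (curve midpoint) and the absolute IC50 (closed-form
solution of $E(c) = 0.5$, `NA` when 0.5 lies outside the asymptotes),
labelled explicitly since screening reports often blur the two.

## Differential 3D analysis

For each drug × line, $\Delta AA = AA_{3D} - AA_{2D}$ is the residual
from the $y = x$ reference on the 2D-vs-3D activity plane. A line is
*decreased* when $\Delta AA < -\tau$; a drug is eliminated when
decreased in at least `min_lines` (default 3) lines. The published
workflow calls decreased lines from the residual plot without a numeric
cutoff; $\tau$ is the explicit, configurable stand-in, default 0.1 in
normalized AA units — large enough to absorb replicate noise in the AA
estimate (empirically ~0.02 SD at triplicate, multiplicative count noise
of 5%), small enough to catch effect sizes an order of magnitude larger.
Ranking of surviving drugs uses the sum of per-line $AA_{obs}$,
descending, ties broken lexicographically by drug id for determinism.

## The synthetic screen generator

The generator emulates the study design: four lines (seeding 600
cells/well, 900 for THJ-21T), 2D and 3D conditions, the printed 5-point
primary series (5.14 µM … 6.2 nM) and a 10-point log-spaced confirmation
series (20 µM … 20 nM) in technical triplicate, imaging every 6 h for
5 days with the analysis window cut at 72 h downstream.

**Kinetics.** Counts are not modelled in the published analysis, so the
generator adopts the simplest kinetic model whose dead fraction is
monotone in drug effect — a two-compartment birth–death system

$$\frac{dL}{dt} = (g - d(c))\,L, \qquad \frac{dD}{dt} = d(c)\,L,
\qquad d(c) = d_{max}\,(1 - E(c)),$$

with closed-form solution used directly (no ODE solver). Defaults:
growth $g = 0.03/\text{h}$ (~23 h doubling, typical of aggressive
carcinoma lines), maximal death rate $d_{max} = 0.05/\text{h}$. Controls
($c=0$) show pure exponential growth and zero expected dead fraction;
the noiseless model conserves $d(L+D)/dt = gL \ge 0$.

**Noise.** Counts are drawn per timepoint as Poisson around the
deterministic expectation (default — appropriate for small segmented
counts), or multiplicative Gaussian with $\sigma = 0.05$ (the condition
used by the recovery benchmarks), or disabled. Each well draws from an
RNG substream derived by hashing its plate/row/column key with the
master seed, so simulated data are invariant to layout order and
byte-reproducible per seed.

**Ground truth.** Active drugs draw $E_{inf} \sim U[0, 0.6]$,
$h$ log-uniform on $[0.5, 3]$, $EC_{50}$ log-uniform within the tested
range; half the drugs (configurable) are inert ($E(c) \equiv 1$),
mirroring the long inactive tail of a real primary screen. Per-line
heterogeneity — real lines differ in sensitivity — is a
$\times 10^{N(0,0.15)}$ EC50 factor and a small clamped $E_{inf}$
perturbation, enough to make lines distinct while keeping across-line
AUC SD low for genuinely broad-acting drugs.

**Planted penetrance effects.** A configured number of drugs (7 of 40 in
the standard design) are penetrance-limited: in a random subset of at
least `min_lines` lines, their 3D EC50 is multiplied by a factor $p$
drawn log-uniform from `p_range` (default $[3, 30]$; the recovery
benchmark uses $[10, 30]$), optionally with an $E_{inf}$ lift. The
magnitude of the real 3D effect is not published; these defaults are
chosen for testability — large enough that the ≥3-line filter should
find them above noise — not as a claim about real effect sizes. Planted
drugs draw their 2D EC50 at least one decade below the top tested
concentration: a drug whose midpoint sits at the top of the series has
essentially no measurable 2D activity, hence nothing for the 3D shift to
remove, and planting it would make the recovery target meaningless.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: spatial drug diffusion within
spheroids (penetrance is a phenomenological EC50 shift), plate edge and
liquid-handling artifacts, growth–death feedback (quiescence, crowding),
segmentation errors correlated across timepoints, batch effects between
plates, and any deviation of real dose–response shapes from the 4PL.

## Image counting

The two-channel counting path mirrors a high-content pipeline: nuclei
are rendered (for fixtures) as 2D Gaussian blobs (sd = radius/2) in the
red nuclear-marker channel, dead nuclei also in the green dead-stain
channel; z-stacks are collapsed by per-pixel maximum projection before
any segmentation. Segmentation is Gaussian smoothing (sd 2 px), global
Otsu threshold, connected components, and an optional
distance-transform watershed for touching nuclei (off by default —
well-separated fixtures do not need it and oversplitting costs more
than merging at the densities tested); components under 20 px² are
discarded. A nucleus is dead when its mean green intensity exceeds a
threshold, by default background mean + 3 × background SD estimated
outside all nuclei — a numeric operationalization of "signal overlap".
Fixtures use 0-based pixel coordinates, x = column. TIFFs are written
16-bit, the native convention of microscope exports.

## Problem sizes and numerical choices

The validation suites use: 1000 random curves for the area-metric
oracle; 200 simulated 10-point triplicate curves (σ = 0.05) for 4PL
recovery, with generating EC50s one decade inside the series (an
edge-of-range midpoint leaves an asymptote unsampled and is not
identifiable — a benchmark on such curves measures the design, not the
fitter); 20 planted screens of 40 drugs × 4 lines × 2 conditions (plus
20 null screens) for filter recovery; and 20 noisy 1024² fixtures of
200 nuclei for counting robustness. Area integrators are plain
trapezoids cross-checked in tests against an independently coded
oracle; ties in all rankings break lexicographically; sample SD over a
single line is reported as 0 with an `insufficient_replication` flag
rather than an error.

## Known limitations

* The elimination rule is a threshold count, not a significance test —
  faithful to the published workflow, which applies none; drugs near the
  τ boundary flip lines stochastically.
* The primary hit rule is top-k by (mean AUC, SD AUC) or explicit
  thresholds; the published selection was a judgment call on a scatter
  plot, so any reproduction of "62 hits" depends on the user's k. The
  mean-based rule is default, with a per-line-maximum option, since the
  publication does not state whether hits required low AUC in every line.
* Curated exclusions are user data (`apply_curation`), not logic: the
  mechanism ships, the clinical judgment does not.
* Endpoint normalization for the primary screen uses same-plate control
  means; plate-to-plate control drift is not corrected beyond that.
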