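---
title: "Classifying intracranial pressure-flow regimes"
author: "icpfr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying intracranial pressure-flow regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpfr)
```

## The scientific problem

Neurocritical care of traumatic brain injury is steered almost entirely by
pressures: arterial blood pressure (ABP), intracranial pressure (ICP), and
their difference, the cerebral perfusion pressure CPP = mean(ABP) -
mean(ICP). The quantity the therapy actually aims to protect — cerebral
blood flow (CBF) — is rarely measured. Pressure-guided protocols therefore
rest on an assumed *pressure-flow relationship* (PFR): that flow follows
the pressure gradient, modulated by cerebral autoregulation (CA).

Over two-hour stretches of monitoring, three qualitative regimes can hold:

* **pPFR** — positive coordination: flow passively tracks CPP, the
  signature of impaired or unengaged autoregulation. This is the regime
  that pressure-oriented models and protocols implicitly assume.
* **zPFR** — no net coordination: functional autoregulation decouples flow
  from pressure, typically through an equilibrium of locally positive and
  negative episodes rather than flat independence.
* **nPFR** — sustained negative coordination: flow moves opposite to CPP,
  violating the pressure-passive assumption in a precise, sign-reversing
  way. Candidate physiology includes metabolically driven flow and
  volume-driven pressure dynamics.

This package implements a model-driven classifier of these regimes for
intervals of multimodal monitoring data (ABP and ICP at 125 Hz,
thermodiffusion brain-tissue perfusion at 1 Hz), together with the
windowed autoregulation indices (Mx, PRx) and the regime-level statistical
analyses that characterise the regimes. Because suitable clinical
recordings are access-restricted, the package ships a first-class
synthetic generator that emulates the relevant signal structure, and every
claim the package makes is tested against it.

## The compartmental model and its inversion

Ignoring spatial structure, CSF and venous compartments, the zero-
dimensional compartmental description of intracranial hemodynamics reduces
to

$$Q(t) \;=\; \alpha_1\,\nabla p(t) \;+\; \alpha_2\,\frac{d}{dt}\nabla p(t),$$

where $\nabla p$ is the perfusion pressure gradient (CPP, mmHg), $Q$ the
global CBF (mL/s), and $\alpha = (\alpha_1, \alpha_2)$ lump the CA control
of vessel-bed conductance and compliance. Both components are constrained
non-negative: that is precisely the pressure-passive (pPFR) assumption,
and time-averaging recovers the textbook cerebrovascular resistance
relation $\alpha_1 = \nabla p / Q$ (`cvr()`).

`forward_flow()` evaluates the model (central differences for the
derivative, one-sided at the ends, missing samples propagating through the
stencil). `estimate_cbf()` inverts it: per 1-min window the parameters are
held constant, and the whole trajectory minimises

$$\sum_{t\ \mathrm{valid}} \big(\alpha_{1,t} p_t + \alpha_{2,t} \dot p_t - q_t\big)^2
 \;+\; \lambda_s \sum_t \lVert \alpha_{t+1} - \alpha_t \rVert^2_w
 \;+\; \lambda_p \sum_t \lVert \alpha_t - \alpha^0 \rVert^2_w ,
 \qquad \alpha \ge 0,$$

where $q$ is the flow reference (observed perfusion, affinely mapped to
the CPP scale by default), the norms are weighted by the squared design
column norms so the penalty weights are scale-free, and the bound
constraint is solved exactly by an active-set non-negative quadratic
program (C++ projected coordinate descent as fallback). The prior anchor
$\alpha^0$ defaults to the time-averaged resistance relation
$\mathrm{mean}(q)/\mathrm{mean}(p)$ (1 model unit when no reference
exists); it only matters when the data term is uninformative, e.g. the
compliance component under constant CPP, which is then flagged
(`alpha2_unidentifiable`).

### Why the roughness weight is large, and what it costs

`lambda_smooth = 150` (smoothing length $\approx \sqrt{\lambda_s} \approx
12$ windows) is the load-bearing choice. The data term alone is
underdetermined — two parameters per window, one observation — so with
weak smoothing the non-negative fit can amplitude-modulate at the 10–30
min scale and partially mimic anti-correlated or alternating perfusion,
which would blunt exactly the calibration slope the classification relies
on. In calibration experiments, weights an order of magnitude smaller let
an alternating-regime interval masquerade as positively coordinated; at
150 the three regimes separate cleanly (the regime-recovery tests and the
acceptance script quantify this).

The cost is resolution of genuine parameter *jumps*: an L2 first-
difference penalty smears a step in $\alpha_1$ over the smoothing length,
so recovery fidelity of the flow trajectory degrades smoothly as the step
size grows. The shipped forward-inverse tests pin the two ends of that
trade-off: r >= 0.99 against truth for modest (2–6%) piecewise-constant
conductance schedules on noiseless data, and r >= 0.9 for coarse 20%
steps under 10% observation noise. An edge-preserving penalty could
sharpen steps but would re-open the modulation loophole; we prefer the
simple scheme with its documented trade-off.

A hard guarantee backs the classification: if the fitted flow ever
correlates negatively with CPP (conceivable only through derivative-term
pathologies), the estimate falls back to a constant-parameter fit and
finally to a pure-conductance fit, so `cor(Q, CPP) >= 0` always holds.

## Posterior calibration and the regime label

Global model flow (mL/s) and local probe perfusion (mL/hg/min) differ by
patient- and placement-specific scale and bias, so the model trajectory is
calibrated to perfusion with a linear correction `m * CBF + b`
(`fit_correction()`). Both signals are standardised to zero mean and unit
variance first; `m` is then the least-squares slope between the
standardised signals — numerically their Pearson correlation — which makes
slopes comparable across intervals regardless of perfusion magnitude. The
sign and size of `m` decide the regime (`classify_pfr()`):

* `m > 0.2` — pPFR,
* `m < -0.2` — nPFR,
* `|m| <= 0.2` (boundary inclusive) — zPFR.

The negative branch is stated here as `m < -0.2`; the symmetric reading is
the only one under which the three labels are exclusive and exhaustive.
The half-width 0.2 of the neutral band is configurable. For reference,
under an independence null at the 120 one-minute samples of a nominal 2-h
interval, |m| stays below 0.2 with probability ~0.97, so the neutral band
is wide relative to estimation noise.

Because the inversion cannot orient flow against CPP, an interval whose
perfusion genuinely opposes CPP yields a strongly negative `m` — the
non-negativity constraint is what converts "the model cannot fit this
interval without a sign change" into an observable, signed quantity.

## Autoregulation indices

`moving_corr()` is the shared computational core: block-average both
signals at a width `w`, emit the Pearson correlation of each window of
`n` consecutive blocks, advance by `step` (window timestamps are window
ends; windows with a missing pair or zero variance are `NA`). On top of
it:

* `mx()` — flow vs CPP, 30-sample correlations of 12-s averages (6-min
  windows), step 60 s. Values near +1 mean pressure-passive flow.
* `prx()` — ABP vs ICP, 30-sample correlations of 10-s averages (5-min
  windows), step 60 s. There is no consensus windowing for PRx; these are
  the common literature conventions and both windows are configurable.

Values above ~0.3 on either index are conventionally read as impaired CA.
`neutral_mx_compare()` implements the epoch-level contrast between
neutral-Mx epochs (|mean Mx| < 0.15) and the remainder, testing one-sidedly
whether neutral epochs have smaller mean PRx — the pattern expected if
their neutrality reflects active autoregulation.

## Regime-level statistics

* `joint_density()` — kernel densities of pooled per-window (PRx, Mx)
  pairs per regime on the common support $[-1,1]^2$ (normal-reference
  bandwidths by default, renormalised to integrate to 1 on the clipped
  support), plus the difference surface of the positive regime against the
  pooled rest.
* `ks2d_two_sample()` — a two-sample two-dimensional Kolmogorov-Smirnov
  test in the Fasano–Franceschini quadrant construction: with every data
  point of either sample as origin, D is the largest absolute difference
  of empirical quadrant probabilities. Significance is by label
  permutation (exact up to Monte-Carlo error, assumption-light); the
  classical asymptotic approximation is available as an option. The
  statistic is evaluated by an $O(N\log N)$ Fenwick-tree sweep (exact for
  tie-free data; a quadratic scan handles ties), which is what makes
  permutation calibration studies affordable.
* `ca_impaired()` / `fit_discriminant()` — the one-parameter family of
  joint-index boundaries $Mx = c\,(1-PRx)$, which passes through
  (PRx, Mx) = (1, 0) and generalises the independent 0.3 thresholds. The
  coefficient is fitted by grid search (step 0.01, ties toward smaller c)
  maximising balanced accuracy of "positive regime iff $Mx > c(1-PRx)$";
  an alternative objective integrates the kernel-density difference over
  the super-boundary region. Both are provided because the boundary can
  be defined either way; on synthetic clouds they agree to within the
  grid resolution.
* `group_compare()` — per-variable pairwise two-sample KS and t-tests with
  group medians and quartiles, flagged at the conventional uncorrected
  thresholds (KS p < 0.005, t p < 0.05); Bonferroni and a permutation
  median test are options, since "difference in medians" claims are
  sometimes wanted as median tests proper.
* `rank_predictors()` — predictor influence on a target signal. The ARD
  route fits a Gaussian process with a squared-exponential covariance
  carrying one length-scale per (standardised) predictor by regularised
  evidence optimisation; importance is the reciprocal length-scale.
  Three safeguards address known pathologies of plain ML-II ARD at
  moderate sample sizes: a weak relevance-shrinkage prior on the inverse
  squared length-scales (spurious structure on a noise dimension gains
  only a few nats of evidence and is suppressed), a backward-elimination
  polish that flattens a dimension and re-optimises unless its structure
  is worth at least ~2 nats, and a degeneracy guard zeroing dimensions
  whose kernel retains no correlation at typical input separations (the
  white-noise direction of the SE kernel). Lasso and ridge routes
  (cross-validated `glmnet`, importance = |standardised coefficient| at
  `lambda.1se`) serve as robustness checks.

## The synthetic generator

`generate_regime_epoch()` builds labelled epochs from a declarative
`synth_spec()`:

* **ABP** (125 Hz): target mean + slow fluctuations + a cardiac pulse
  train (half-sinusoid systolic upstroke, exponential diastolic decay,
  pulse-pressure amplitude) + Gaussian noise. All components are
  mean-centred, so the epoch mean stays within 1 mmHg of the target.
* **Slow waves**: three sinusoids with periods in the 1–10 min band drawn
  uniformly in *frequency* (a red-spectrum flavour consistent with slow
  vasogenic waves) plus a lighter AR(1) drift (amplitude weights 0.9 and
  0.4). These weights are a calibration-free design choice; they were
  fixed once so that the alternating-gain construction below is balanced
  by construction, and are not fitted to any data.
* **ICP** (125 Hz): target mean + a 0.2-gain transmission of the ABP slow
  wave (so PRx is exercised over its range) + an independent 1 mmHg slow
  component + noise.
* **Perfusion** (1 Hz): baseline + gain(t) x (CPP deviation) + noise,
  where the deviation is taken about the mean CPP of each constant-gain
  segment. For constant-gain regimes this is exactly the global-mean
  construction; for the alternating zPFR schedule (+g/-g in equal 15-min
  blocks) it prevents unphysical step discontinuities in perfusion at
  block boundaries and makes the positive and negative episodes balance.
  Probe-placement heterogeneity is emulated by a seeded per-epoch jitter
  of baseline (±20%) and scale (±10%).
* At the defaults the coordination signal-to-noise ratio,
  |gain| x sd(slow CPP) / noise sd, is 2.

What the generator does *not* emulate: physiologically detailed CA control
laws, respiration- and Windkessel-coupled waveform morphology, sensor
drift, or inter-channel clock skew. Passing the recovery tests therefore
demonstrates that the method identifies prescribed pressure-flow
coordination under realistic noise, gaps and artifacts — not that it is
validated on clinical data, which remain access-restricted.

## Quality control and interval extraction

`extract_intervals()` finds maximal runs with ABP and ICP present and
perfusion gaps of at most 10 min (probe recalibration), tiles them
greedily left-to-right into non-overlapping intervals of at most 140 min,
and keeps a final remainder only if it is at least 100 min. `qc_filter()`
then applies, in physical units: (i) negative ABP, or ABP above the
epoch-level 99.8th percentile by a configurable factor; (ii) negative
perfusion, any sample above 130 mL/hg/min, or any 5-min mean above 95;
(iii) negative ICP, or ICP above 100 mmHg continuously for more than 5
min on 1-s averages, a run being broken by any second at or below the
threshold. Every violated rule is reported with its time ranges, and QC
never raises on data content.

One rule needs interpretation: "ABP outlier among the 99.8th percentile"
is ambiguous, and with a factor of 1.0 on the epoch percentile *every*
interval of clean data would fail (0.2% of samples exceed their own
percentile by definition). The default factor is therefore 1.2, and both
the factor and the percentile basis are configurable in `qc_rules()`.

## Numerical choices and degenerate inputs

* Block averaging uses left-aligned half-open windows, timestamps at block
  starts; all-missing blocks stay `NA`.
* The QP solver runs an exact active-set method with a projected
  coordinate-descent fallback (tolerance 1e-12); non-negativity is
  enforced by construction, not by post-hoc clipping of reported values.
* Correlation windows with zero variance are `NA`, never 0.
* `fit_correction()` requires 30 joint samples and positive variance in
  both signals; pairs with missing members are dropped listwise.
* The discriminant grid search breaks ties toward the smaller coefficient;
  `classify_pfr()` places the exact boundary values in the neutral band.
* Permutation p-values use the add-one estimator (count + 1)/(n_perm + 1)
  and a fixed seed argument for reproducibility.
* Pipeline stage seeds are derived from the master seed by fixed offsets;
  the manifest records content digests, and re-running a configuration
  reproduces them exactly.

## Problem sizes used by the test-suite

The shipped tests run the full path on 2-h epochs (100 seeds per regime
for the recovery properties), 50-seed forward-inverse batches at 240
windows, a 500-replicate permutation-calibration study of the 2D KS test
at n = 200 per sample with 999 permutations, 20-seed discriminant
recoveries, and 50-seed ranking batches at n = 300 samples and 5
predictors. These sizes were chosen as the smallest at which the binomial
or Monte-Carlo error of each checked proportion is well below the margin
being asserted.

## Known limitations

* The inversion scheme is a declared stand-in satisfying the stated
  constraints (1-min stationarity, non-negativity, Eq.-consistency);
  other regularisations could be substituted behind the same interface.
* Absolute flow scale is not identifiable without flow observations; all
  downstream conclusions use the standardised slope, and reported
  model-flow units are nominal.
* The linear CBF-perfusion calibration is deliberate; the true
  relationship is likely nonlinear and probe-site dependent.
* Classification is per-interval; within-interval regime switching
  (common in highly variable zPFR cases) is summarised, not segmented.
* Single-index thresholds (0.3) and the joint-boundary coefficient depend
  on the index windowing; they travel with the window configuration.
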