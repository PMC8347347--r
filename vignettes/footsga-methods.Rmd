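---
title: "Statistical gait analysis from foot-switch basography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical gait analysis from foot-switch basography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Basography records foot-floor contact with three binary switches per foot,
placed under the heel and the first and fifth metatarsal heads.  A closed
switch (sensor loaded) reads 1.  Sampled at a fixed rate (2 kHz in the
emulated protocol), the three channels of one side encode, sample by
sample, one of four foot-floor contact phases:

| heel | met1 | met5 | phase |
|------|------|------|-------|
| 1 | 0 | 0 | **H** — heel contact |
| 1 | any metatarsal closed | | **F** — flat-foot contact |
| 0 | at least one closed | | **P** — push-off |
| 0 | 0 | 0 | **S** — swing |

The mapping is total over the eight switch states, so `encode_phases()`
never fails.  A *gait cycle* (stride) runs from one contact onset — a
transition from swing into any contact phase — to the next contact onset of
the same foot.  The run-length-encoded phase string of a cycle is its
class: `HFPS` is the physiological sequence and defines a *typical* cycle;
every other string (`PFPS`, `PS` = forefoot initial contact, `FPS` =
flat-foot initial contact, `HFHFPS` = unstable heel contact, ...) is
*atypical*.  The classifier is open-vocabulary: the label *is* the string,
so previously unseen contact sequences are handled without any template.

Statistical gait analysis draws its power from volume: a five-minute
continuous walk yields 250–300 cycles per side, enough to estimate per-class
percentages, phase-duration distributions and their group contrasts.

## Debouncing

Mechanical switches bounce: spurious toggles of a few milliseconds around
contact events.  `debounce()` removes every maximal constant run strictly
shorter than a threshold by merging it into the *preceding* run, iterating
earliest-shortest-first until a fixpoint.  Properties that the test suite
asserts against an independently coded oracle:

* idempotence — filtering a filtered signal is a no-op;
* no interior run below the threshold survives;
* runs touching the recording boundary are never altered (their true
  extent is unobserved);
* no level transition moves by more than the threshold, and since the
  filter looks forward as well as backward there is no systematic lag.

The default threshold is 20 ms: roughly an order of magnitude below
physiological phase durations (~100–500 ms) and above realistic bounce.
The protocol's acquisition hardware applies its own anti-bounce filter with
an unpublished time constant; 20 ms is this package's choice, exposed as a
parameter.  A second run-length pass with the same threshold operates on
the encoded four-level signal (`encode_phases(min_phase_s = )`), because
interleaved toggles on different channels can still produce one-or-two
sample phases after encoding.

## Segmentation choices

* Cycles open at *any* contact onset, not only heel strike.  Opening at
  heel strike only would make forefoot-initial-contact cycles (`PFPS`,
  `PS`) — the most clinically interesting classes — invisible.
* Partial segments before the first and after the last onset are
  discarded: their class cannot be determined.
* Segments longer than `max_cycle_s` (default 3 s, about three times a
  normal stride) are treated as pauses.  They are excluded from every
  statistic but returned in the `discarded` attribute, never silently
  dropped.
* A cycle belongs to the walking-path region (straight or U-turn) that
  contains its *onset*.  Onset tagging is deterministic and makes the
  per-region atypical percentages additive: with every onset covered by an
  annotation, straight + turn atypical percentage equals the total
  atypical percentage exactly, because all three share the side's total
  cycle count as denominator.

## Spatio-temporal parameters

* **Walking speed** pools distance over time: with $k$ timed passages of a
  path of length $L$, $v = kL / \sum_i t_i$.
* **Cadence** defaults to cycles over the full recording (turns included)
  and is flagged with its mode; a straight-only mode divides straight-walk
  cycles by total straight time.  Because turning strides are quicker and
  shorter, full-recording cadence runs a few cycles/min above steady-state
  straight-line cadence.
* **Double support** is the fraction of a cycle with both feet in contact
  (neither side in swing), averaged over the reference side's cycles.  The
  literature is ambiguous between this *total* definition (both
  double-support periods) and an *initial-only* one; both are implemented,
  with `total` as default.  At typical stance fractions of ~56–58% the
  total definition predicts $2 \times \text{stance} - 100 \approx$ 12–15
  %GC, which is what the pipeline reports.
* **Phase durations** are expressed in %GC over typical cycles only;
  atypical cycles have no canonical H/F/P/S decomposition.
* **Atyp** normalises the atypical-cycle percentage by self-selected
  speed, $\mathrm{Atyp} = \%\text{atypical} / v$, making slow and fast
  walkers comparable.

## Statistical battery

* **Normality** is tested with the Lilliefors statistic (Kolmogorov–
  Smirnov distance from a normal with estimated mean and SD).  Because the
  estimated-parameter null is not the classical KS distribution, the
  p-value comes from a seeded Monte-Carlo null (default 10,000
  simulations); a null table can be reused across tests of equal size.
  The suite verifies a 5% ± 1.5% type-I error at $\alpha = 0.05$.
* **Two-group comparisons** use Student's t (equal-variance, two-tailed)
  when both samples pass the normality screen, otherwise a rank test.  For
  two independent groups the correct rank test is the Wilcoxon rank-sum
  (Mann–Whitney); a paired signed-rank variant exists for paired designs.
  The method actually used is recorded in the result.
* **Two-way ANOVA** (`Group x Side`, one value per subject-side) with
  Tukey-adjusted post-hoc comparisons tests the per-side gait parameters.
  Sides enter as roles (more-/less-affected for patients,
  dominant/non-dominant for controls).  A constant response returns a
  flagged no-effect table instead of NaN.
* **Effect sizes** use Hedges' $g$: the mean difference over the
  df-weighted pooled SD, multiplied by the small-sample correction
  $J = 1 - 3/(4(n_1+n_2)-9)$ (appropriate for $n \le 20$; can be disabled,
  which reproduces the uncorrected quotient exactly).
* **Subgroup selection**: patients with Atyp above the control mean plus
  one sample SD (controls contribute side-averaged values) form the
  above-threshold subgroup with an abnormal amount of atypical cycles.
* **Correlation** between Atyp (more-affected side) and the motor score is
  the Pearson coefficient of the least-squares fit, with a two-sided
  t-distribution p-value and a 95% CI from 1000 seeded pair resamples.
  The default interval is BCa (bias-corrected and accelerated, jackknife
  acceleration) with a percentile option; degenerate bootstrap
  distributions fall back to percentile.  Coverage is verified by
  simulation (true $\rho = 0.6$, $n = 20$: 95% ± 3%).

## The synthetic cohort generator

No public recordings exist for this kind of protocol, so the generator is
a first-class module: it emulates the acquisition end to end and every
claim the test suite makes about the pipeline is made against its ground
truth.

What it emulates:

* ~5-minute walks, back and forth over a 9-m straight path with ~2.5-s
  U-turns; turning strides at 0.75 of the straight stride period (turns
  use shorter, quicker steps);
* per-group walking speed (PD 1.01 ± 0.25, controls 1.08 ± 0.17 m/s) and
  stride-period models, with within-subject cycle-to-cycle jitter;
* per-cell (group x side-role) typical phase profiles and atypical rates
  per region, taken from published cohort summaries; class composition
  among atypicals follows the published class prevalences, with the
  remainder split over FPS, HFHFPS and an open "other" category realised
  as random legal contact sequences;
* switch channels reconstructed to satisfy the phase truth table at every
  sample (metatarsal choice randomised per run), the right side
  phase-locked half a stride after the left — which is what produces
  physiological double support of ~12–15 %GC;
* isolated sub-threshold switch bounce;
* a motor score linked to the true speed-normalised atypical percentage.

**Between-subject heterogeneity.**  Published per-side SDs of the atypical
percentage are of the same order as the means, and roughly half the
patients in such cohorts sit at control-level values.  A single log-normal
severity cannot reproduce that structure, so severity is a two-component
mixture: each patient is *gait-affected* with probability 0.5 (an offset
of 2.4 on the atypical log-odds); within components, per-side severities
are log-normal on the odds scale (sdlog 0.5 for patients, 1.5 for
controls) with a between-side correlation of 0.4.  Per-region base odds
are calibrated by quadrature so that the expected rates match the
configured targets exactly.  These parameters were fixed once, by matching
the published group means and the qualitative cohort structure
(above-threshold subgroup of roughly half the patients, group effect
detectable in ≥90% of cohorts), and are exposed in `synth_config()`.

**Motor-score link.**  The score is flat at the intercept below a knee of
15 Atyp units and rises linearly (slope 0.4) above it, with Gaussian noise
of SD 2.5 for gait-affected and 8 for gait-unaffected patients.  The
rationale is clinical: the motor score is a composite, and for patients
whose gait is near-normal it is dominated by non-gait symptoms (tremor,
rigidity), which both flattens and widens its relation to Atyp at the low
end.  A homoscedastic straight-line link was evaluated first and rejected:
truncating a sample from below almost never *increases* the correlation
under such a link (the retained variance shrinks), so it cannot reproduce
the characteristic strengthening of the correlation in the above-threshold
subgroup.  Setting `updrs_knee = 0` and equal noise SDs restores the plain
linear model for sensitivity analyses.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: ground-reaction forces and sensor mechanics
beyond binary contact; freezing-of-gait and festination episodes;
medication-state fluctuation during the walk; fatigue drift; annotation
error in the manual straight/turn labels (annotations are exact by
construction); and any nonlinearity of the true score-gait relation beyond
the hinge.

## Numerical choices

* Strict-inequality debounce threshold with a $10^{-9}$ tolerance; a run
  of exactly the threshold length survives.
* Earliest-shortest tie-break makes the run-merge filter deterministic.
* Intervals are half-open `[start, end)`; times are seconds from the
  recording start; a cycle's onset sample is `round(start_s * fs) + 1`.
* Phase runs are realised with a 50-ms floor so that no legitimate run can
  be destroyed by the default debounce pass; the swing run absorbs
  rounding so that run counts partition the cycle exactly.
* Monte-Carlo p-values use $(1 + \#\{D^* \ge D\})/(n_{sim}+1)$, which is
  exact under the null.
* Sample SD ($n-1$) everywhere, including the subgroup threshold.
* Bootstrap resamples with zero variance are dropped; a point-mass
  bootstrap distribution or an undefined bias correction falls back to the
  percentile interval; interval ends are clipped to $[-1, 1]$.
* Cohort tables are written with 1-decimal parameter values and 4-decimal
  p-values.

## Problem sizes used by the test suite

The suite exercises the full pipeline at reduced scale — 100–500 Hz
sampling and 0.4–3-minute walks — which preserves every rate and cohort
parameter while keeping ~90 cycles per side; the replicated cohort checks
run twenty 20+20-subject cohorts.  The acceptance script, by contrast,
runs one full-scale cohort (five-minute walks at 2 kHz) through the entire
pipeline.

## Known limitations

* The generated control-side SDs (~6–9 percentage points) are wider than
  the published per-side control SDs; that width is what makes the
  published control-referenced threshold and subgroup structure
  reproducible, and the published spread statistics are themselves not
  mutually consistent under any two-parameter unimodal model.  The
  above-threshold subgroup comes out at ~8–12 of 20 patients rather than
  exactly 8.
* Speed, severity and class draws are independent across subjects; real
  cohorts correlate disease severity with speed, which would strengthen
  the Atyp contrast further.
* Double support inherits the ambiguity of its definition; compare modes
  before comparing cohorts.
* With ~90–300 cycles per side, per-class percentages for rare classes
  carry large binomial error; per-class inference should pool classes or
  use the full five-minute protocol.
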