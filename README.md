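# footsga — Statistical Gait Analysis of Foot-Switch Basography

`footsga` characterises human gait from bilateral **foot-switch**
recordings: three binary contact sensors per foot (heel, first and fifth
metatarsal heads) sampled at kHz rates during a prolonged continuous walk.
It is aimed at movement-analysis and clinical-research groups who study
subtle gait dysfunction — in particular in Parkinson's disease (PD) —
through the *foot-floor contact sequence* rather than through kinematics.

## The method

Each sample of the three channels encodes one of four contact phases:

* **H** — heel contact (only the heel switch closed)
* **F** — flat-foot contact (heel plus at least one metatarsal switch)
* **P** — push-off (metatarsal switch(es) only)
* **S** — swing (no switch closed)

After an anti-bounce run-length filter, the phase signal is segmented into
gait cycles at contact onsets (S → any contact phase).  The
run-length-encoded phase string of a cycle is its class: `HFPS` is the
physiological, *typical* cycle; anything else (`PFPS`, `PS` — forefoot
initial contact; `FPS` — flat-foot initial contact; `HFHFPS` — unstable
heel contact; ...) is *atypical*.  Over a five-minute walk (~270 cycles
per side, U-turns included) the package computes per side:

* % typical / % atypical cycles, per-class percentages, and atypical
  percentages split over straight walking vs U-turning (additive by
  construction: straight + turn = total);
* phase durations in %GC over typical cycles; cadence; double support;
* walking speed from timed straight passages, *v* = *kL* / Σ*tᵢ*;
* the speed-normalised atypical percentage **Atyp = %atypical / v**.

The cohort layer runs the statistical battery: Lilliefors normality
screening with Monte-Carlo p-values, Student's t or Wilcoxon rank-sum
comparisons, two-way Group × Side ANOVA with Tukey post-hoc, Hedges'
*g* = *J*·(M₁−M₂)/SD\*pooled with the small-sample correction
*J* = 1 − 3/(4(n₁+n₂)−9), selection of the patient subgroup with
Atyp > mean(Atyp_control) + 1·SD(Atyp_control), and seeded bootstrap (BCa)
confidence intervals for the Pearson correlation between Atyp and a motor
score (UPDRS-III-like).

Because no public recordings of this kind exist, the package ships a
first-class synthetic cohort generator (`simulate_cohort()`) that emulates
the full acquisition — 9-m back-and-forth walks, per-group speed and
stride models, per-cell atypical rates, switch bounce, a severity mixture
and a linked motor score — with a per-cycle ground-truth table, so every
pipeline stage is testable end to end.

## Worked example

```r
library(footsga)

cfg    <- synth_config(n_pd = 6, n_control = 6, recording_minutes = 2,
                       sampling_rate = 200, seed = 42)
cohort <- simulate_cohort(cfg)
df     <- analyze_cohort(cohort, config = run_config(seed = 43))
report <- cohort_report(df, run_config(seed = 43))
print(report)
```

```
Cohort gait parameters (mean per group-side cell):
          parameter more_affected_mean more_affected_sd less_affected_mean ...
              speed                1.0              0.3                 NA
            cadence               55.4              4.6                 NA
 double_support_pct               11.4              2.9                 NA
           n_cycles              110.8              9.6              110.8
        pct_typical               81.3             20.0               90.2
                  H               11.3              3.9                9.0
                  F               18.3              3.5               19.7
                  P               25.9              4.5               26.8
                  S               44.6              2.2               44.5
       pct_atypical               18.7             20.0                9.8

Atypical cycles by walking-path region:
        parameter more_affected_mean more_affected_sd less_affected_mean ...
 straight_walking               10.3             12.7                3.5
        u_turning                8.5              7.5                6.2

Atyp threshold (control mean + SD): 17.5; 2 patients above

Atyp vs motor score:
  whole PD group:  Pearson r = 0.818 (p = 0.04659, n = 6); bootstrap 95% CI [-0.906, 0.991] (bca, 1000 resamples)
```

Reading the output: the patients' more-affected side produced 18.7% atypical
cycles against ~6–12% on control sides, with the straight/turn split adding
up to the total; typical-cycle phase durations and double support
(11.4 %GC PD vs 13.5 %GC controls) are near-normal, which is exactly the
pattern that makes atypical-cycle counting a more sensitive marker than the
classical spatio-temporal parameters.  Two of six patients exceeded the
control-referenced Atyp threshold (with this miniature example's subgroup
of 2, no subgroup correlation is fitted; full-scale cohorts give a subgroup
of ~10).  The whole-group correlation between Atyp and the motor score is
r = 0.818 with a wide bootstrap interval, as expected at n = 6.

Per-subject analysis is available directly:

```r
sub <- cohort$subjects$pd01
res <- analyze_subject(sub$left, sub$right, sub$annotations)
head(cycle_table(res))   # start, end, class, region of every cycle
```

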