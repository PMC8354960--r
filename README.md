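# choicerep

Simulation and preregistered analysis of **value-based choice repetition
(hysteresis) under transcranial direct current stimulation (tDCS)**.

When people choose repeatedly between options, they tend to repeat their
previous choice, and repeating is faster than switching. Attractor-network
models explain this by residual neural activity: after a winner-take-all
decision the winning population decays back to rest only slowly, giving
the previous winner a head start on the next trial — a head start that
should grow under depolarizing (anodal) and shrink under hyperpolarizing
(cathodal) stimulation. `choicerep` is for researchers who want to study
this mechanism in a value-based coin-collection game end to end without
human data: it generates the experimental design, simulates a cohort of
model participants, and runs the complete preregistered statistical
pipeline on the resulting trial logs.

The package provides three layers, each independently usable and tested:

* **Design engine** — measurement blocks over SN/LF value–distance
  trade-offs; per-distance indifference points r\*(d) from logistic
  psychometric fits (midpoint where P(LF) = 0.5) with linear
  interpolation; an eligibility screen (r\* < 0.7 / r\* > 0.3 feasibility
  for the two bias types); bias/bias/target triplets with ratios at
  r\*(d) ± 0.30 and a fixed 500 ms interval before each target;
  counterbalanced two-session sham/anodal/cathodal plans; grid placement
  with a 90-degree separation constraint.
* **Synthetic participant** — a two-population attractor reduction
  (compiled Euler–Maruyama core),

  dx_i = [−λ x_i + w_self g(x_i) − w_inh g(x_j) + ν V_i + π] dt + σ √dt η_i,
  g(x) = max(x, 0),

  with hyperbolic subjective value V = value / (1 + k·distance),
  exponential inter-trial decay of residual activity (time constant τ,
  scaled by 1 + c·π so depolarization slows decay), threshold-crossing
  decisions and decision times, and cohort-level parameter heterogeneity.
* **Preregistered analysis** — sham-pooling check, bias-success filter,
  repetition index (LF% after LF bias − LF% after SN bias), log
  decision-time contrasts, paired t tests with one-tailed conventions,
  Hedges g (averaged-SD standardizer with small-sample correction J = 1 −
  3/(4(n−1)−1)), one/two-factor repeated-measures ANOVAs with partial
  eta squared, Holm correction, and noncentral-t sample-size inversion.

## Worked example

The scripts under `analysis/` form the study workflow; each is a thin
driver over exported functions and writes its tables to `results/`.

```sh
Rscript analysis/01_power.R
Rscript analysis/02_simulate_cohort.R
Rscript analysis/03_preregistered_analysis.R
Rscript analysis/04_model_properties.R
```

`01` inverts the noncentral t distribution and prints

```
required sample size for d = 0.4, power 80%, two-tailed: 52
achieved power at n = 52: 0.8078 (at n = 51: 0.7999)
```

i.e. 52 participants are needed before power first reaches 80%. `02`
recruits 80 synthetic participants, calibrates each one's indifference
points from a 150-trial measurement block, excludes those whose
discounting cannot support the ±0.30 bias manipulation, and writes the
choice log:

```
simulated cohort: 58 eligible of 80 recruited (22 excluded), 73080 choice records
```

`03` replays the preregistered pipeline on that log:

```
sham repetition: LF% 61.02 after LF bias vs 40.14 after SN bias (index 20.88 points)
H1.1 LF% after LF vs SN bias (sham): t(57) = 8.311, p = 1.05e-11 (one-tailed), g = 1.751
H1.2 decision time switch vs repetition (sham): t(57) = 5.314, p = 9.2e-07 (one-tailed), g = 0.230
H2.1 (repetition index ~ tDCS):  F(2,114) = 0.726, p = 0.486
H2.2 (log dt ~ tDCS):            F(2,114) = 0.083, p = 0.921
```

Read: the synthetic cohort shows robust choice repetition (targets after
an LF bias are chosen LF about 21 percentage points more often, and
repeated choices are ~37 ms faster than switches), while the stimulation
ANOVAs are null — the committed default agent has zero polarization
sensitivity, so the pipeline reproduces exactly the qualitative pattern
it is designed to detect. `04` switches polarization sensitivity on
(magnitude 0.15) and tabulates the mechanism's predictions: the
repetition index collapses when the target interval grows from 500 to
1500 ms, and orders anodal > sham > cathodal with the reverse ordering
for decision times.

Smaller pieces work directly:

```r
library(choicerep)
hedges_g_av(56.15, 17.53, 40.24, 15.51, 52)  # 0.947 -> 0.95
required_n_paired(d = 0.4)                   # 52
current_density(1, 5, 5)                     # 0.04 mA/cm^2
```

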