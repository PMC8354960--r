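---
title: "Modelling and analysing value-based choice repetition under tDCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing value-based choice repetition under tDCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

People tend to repeat their immediately preceding decision — choice
hysteresis. Attractor-network accounts explain this through residual
neural activity: after a winner-take-all decision, the winning population's
activity decays back to rest only gradually, so if the next trial starts
soon, the previous winner begins with a head start. The same account
predicts that membrane depolarization (anodal tDCS) slows that decay and
so amplifies repetition, while hyperpolarization (cathodal tDCS) weakens
it, and that repeated choices are faster than switches.

`choicerep` implements the full machinery needed to study this in a
value-based coin-collection game, without any human data: a design engine
that builds indifference-point-calibrated trials, a synthetic participant
implementing the attractor mechanism, and the preregistered statistical
pipeline. Every stage is an exported, tested function; the numbered
scripts under `analysis/` chain them into the study workflow.

## The decision game and the design engine

Each trial offers a **small/near (SN)** coin and a **large/far (LF)** coin
on a 20 x 20 grid. The SN coin is 2 or 3 fields away; the LF coin is 1, 4,
8 or 12 fields further (the *extra distance* d) and worth 65–85 credits,
with the SN value a fraction (*ratio*) of the LF value. Since walking costs
time, the choice trades value against distance.

The **measurement block** (`make_measurement_trials()`) samples ratios
uniformly on [0.20, 0.95] at a constant 500 ms inter-trial interval (ITI).
From its choices we estimate, per anchor distance, the **indifference
point** r\*(d) — the ratio at which P(choose LF) = 0.5 — by
maximum-likelihood logistic regression of choice on ratio
(`fit_psychometric()`). The logistic form is our choice: the original
procedure is described only in an unavailable supplement, and a logistic
in ratio is standard psychometric practice with a directly interpretable
midpoint. Midpoints are clipped to [0.05, 0.95]; all-one-side or perfectly
separated data are flagged degenerate and clipped rather than crashing,
which mirrors how extreme discounters are handled by the eligibility rule.
Non-anchor distances are filled in by linear interpolation
(`estimate_indifference_profile()`) — the minimal assumption consistent
with "interpolated".

**Bias trials** set the ratio 0.30 *above* r\*(d) (SN clearly better) or
0.30 *below* (LF clearly better). We read "30% above/below the
indifference point" additively, because the stated feasibility bounds —
r\* below 0.7 for SN bias, above 0.3 for LF bias — are exactly the additive
bounds that keep the shifted ratio inside (0, 1). A player needs at least
two feasible distances **for each bias type** (`check_eligibility()`);
blocks contain both triplet types, so a single feasible type would leave
the design unconstructible. Players failing the screen end after the
measurement block, as in the human protocol.

**Triplets** (`make_triplet_blocks()`) are two same-type bias trials
followed by a neutral target at r\*(d), target distance uniform on 1–12.
Both bias trials share one type so that "the preceding bias" is
well-defined for the repetition analyses. The ITI before the target is
always 500 ms (hysteresis is strongest at short intervals); the triplet's
other two ITIs are 500 and 1500 ms in random order, masking the triplet
structure. We default to 40 triplets (120 trials) per experimental block,
consistent with the ~480 trials observed across the four 6-minute blocks.

**Counterbalancing** (`make_session_plans()`): each session is one
measurement plus four experimental blocks, with real stimulation in
contiguous blocks 2–3 or 4–5 and sham in the others; across a
participant's two sessions the sham/real order flips and the polarity
switches between anodal and cathodal; the four resulting scenarios are
cycled across the cohort.

`realize_on_grid()` places the two coins at the required city-block
distances with at least 90 degrees between the avatar-to-coin vectors, so
approaching one coin retreats from the other.

## The synthetic participant

The agent (`simulate_decision()`, `simulate_session()`) is a two-unit
rate reduction of the biophysical attractor network: one unit per option,
each with self-excitation, mutual inhibition and additive noise,

$$dx_i = \left[-\lambda x_i + w_{self}\,g(x_i) - w_{inh}\,g(x_j)
        + \nu V_i + \pi\right]dt + \sigma\sqrt{dt}\,\eta_i ,
        \qquad g(x) = \max(x, 0),$$

integrated by Euler–Maruyama until one rectified activity crosses the
threshold, which is the choice; decision time is the crossing time plus a
non-decision time t0. The full conductance-based model is used in the
literature only for qualitative predictions (residual-activity decay,
polarization effects); this reduction preserves exactly those mechanisms
at desk scale. Subjective value is hyperbolic in distance,
$V = \text{value} / (1 + k\,\text{distance})$ — distance is a time proxy
in this paradigm and hyperbolic discounting is the field default — giving
the analytic indifference ratio
$r^*(s, d) = (1 + ks)/(1 + k(s+d))$ used as ground truth in the tests.

Between trials the state decays exponentially with time constant
$\tau$ (`apply_iti_decay()`); at block starts it resets to rest. tDCS
enters twice, and either pathway can be zeroed independently: the
polarization offset $\pi$ adds to both units' drive (anodal positive,
cathodal negative, sham zero), and the decay constant is scaled by
$1 + c\,\pi$, so depolarization slows the decay of residual activity.
Trials that reach the timeout are resolved toward the currently larger
activity and flagged — the human task has no no-response trials.

### The committed parameter set ("default-2021")

| parameter | default | units | why |
|---|---|---|---|
| leak $\lambda$ | 4 | 1/s | sets the relaxation scale; below $w_{self}$ so winners self-sustain |
| $w_{self}$ | 6 | – | with $w_{inh}$ gives a symmetric saddle: winner-take-all |
| $w_{inh}$ | 8 | – | inhibition dominance, forcing a single winner |
| noise $\sigma$ | 0.5 | u/√s | sets bias-trial success near 80%, as observed in humans |
| threshold | 1 | u | defines the activity scale |
| dt | 0.001 | s | 1 ms Euler step, standard for such simulations |
| t0 | 400 | ms | non-decision time; total decision times ~700–800 ms |
| $\tau$ | 150 | ms | residual decay; yields a repetition index of ~15–25 points at 500 ms ITI and near zero at 1500 ms |
| polarization | 0 | u/s | sham; the committed cohort has zero tDCS sensitivity, matching the human outcome |
| c (decay coupling) | 2 | 1/(u/s) | ±0.15 polarization scales $\tau$ by 1.3/0.7 |
| k | 0.2 | 1/field | moderate discounting; indifference ratios span ~0.38–0.88 over the design's distances |
| value gain $\nu$ | 0.09 | (u/s)/V | drives threshold crossings within a few hundred ms |
| max time | 3 | s | timeout |

These values were fixed once by forward simulation of single blocks before
any cohort-level test was written, targeting four observable scales:
~50% LF choice at the indifference ratio (exact by symmetry), ~80%
bias-trial success, decision times in the 700–800 ms range, and a sham
repetition index of the order of 15–25 percentage points. The
polarization-direction properties are asserted at magnitude 0.15, above a
sensitivity floor of about 0.1 below which the Monte-Carlo ordering is not
reliably resolvable at feasible trial counts.

Cohorts (`simulate_cohort()`) draw per-participant k and $\tau$ from
moment-matched lognormal populations (defaults: k mean 0.30, SD 0.55;
$\tau$ mean 150 ms, SD 50 ms). The wide k spread is deliberate: shallow
discounters (small k) have indifference points near 1 at every distance,
fail the SN-bias feasibility rule and are excluded after the measurement
block — the simulated exclusion fraction (~25–30% of 80 recruited)
emulates the human funnel. Note the asymmetry: under the additive bias
rule, *steep* discounting never becomes infeasible, because LF bias
remains constructible at short distances for any k; exclusion is driven
by the shallow tail. Every eligible participant plays both sessions with
a per-session re-estimated profile; a participant whose second-session
profile fails the screen is also excluded, standing in for the human
study's technical dropouts.

## The preregistered analysis

`preregistered_report()` runs, in order: the sham-pooling check (paired t
of sham LF% across sessions; data are pooled regardless, with a flag if
the check is significant, so the pooling decision is always explicit
rather than silently conditional), the bias-success filter (by default
conditioning on the trial immediately preceding the target), then

* **H1.1** one-tailed paired t of per-participant LF% after LF-bias vs
  after SN-bias targets, sham only; the difference is the **repetition
  index** in percentage points;
* **H1.2** one-tailed paired t of per-participant mean log decision times,
  switch vs repetition targets (the log transform reduces right skew;
  Hedges g is reported on the raw-ms scale, which is the scale on which
  the published means and SDs reproduce their g values);
* **H2.1/H2.2** one-way repeated-measures ANOVAs (anodal/cathodal/pooled
  sham) of the repetition index and of mean log decision time over all
  target trials, each with directional Holm-corrected post hocs;
* exploratory: sham-first vs sham-second overall LF%, stimulation effects
  on overall LF% and on bias success, the stimulation x trial-type ANOVA
  on log decision times, and the manipulation check by trial role.

Percentages are computed per participant and then averaged — the published
SDs are between-participant. Effect sizes: Hedges
$g = \frac{m_1 - m_2}{\sqrt{(s_1^2+s_2^2)/2}}\left(1 - \frac{3}{4(n-1)-1}\right)$
(the estimator that reproduces both published values from the published
summary statistics), partial eta squared as SS_effect/(SS_effect +
SS_error) with total-SS eta squared alongside. ANOVAs require complete
balanced designs and refuse to impute. `required_n_paired()` inverts the
noncentral t distribution (df n−1, noncentrality d√n) for the smallest n
reaching the target power; at d = 0.4, alpha = .05, power .80 it returns
52. The Bayesian repeated-measures ANOVA of the original analysis plan is
out of scope: its Bayes factors depend on a specific package's default
priors and on the raw human data.

## What the generator does and does not emulate

The synthetic cohort reproduces the *structure* the analysis assumes:
triplet blocks, counterbalanced stimulation, residual-activity hysteresis
that decays with ITI, faster repetitions than switches, realistic
bias-success and exclusion rates, and between-participant variability in
discounting and decay. It does **not** model: a generative value function
calibrated to human LF rates (none is published, so quantitative matches
to the human test statistics are out of reach by design), motor/movement
time beyond a constant t0, practice effects across sessions, tDCS
after-effects carrying into sham-second blocks (the human data showed no
evidence of any; off by default), or sequential dependencies beyond
one-trial residual activity. Passing tests therefore validate the
pipeline's correctness and the mechanism's qualitative predictions, not
any quantitative claim about human behavior.

## Numerical choices and degenerate inputs

* Ties at threshold within one Euler step: larger activity wins, exact
  ties by a coin flip from the same RNG stream.
* Credit values are rounded half-away-from-zero and clamped to
  [1, LF − 1]; logged ratios are recomputed from the rounded values, so
  empirical ratio bounds carry a rounding slack of 0.5/65.
* All-zero paired differences return the defined limit t = 0, p = 1;
  zero-variance differences with nonzero mean raise a degenerate-test
  error.
* Zero-SS ANOVA effects report F = 0, p = 1 rather than 0/0.
* All randomness flows from one master seed; cohorts derive
  per-participant substream seeds from it, so runs are byte-reproducible
  (asserted on the CSV artifacts) and participants can be re-simulated
  independently.

## Problem sizes used by the tests and scripts

The committed workflow simulates 80 recruited participants (~73k trials,
a few seconds). The test suite uses single-block Monte Carlo of 5–10k
triplets for the hysteresis and polarization properties, 10k-trial
fixtures for the repetition probabilities, 200 replicate 20-participant
null cohorts for the type-I-error check, and 12-participant cohorts for
the end-to-end contracts; these sizes put the Monte-Carlo standard errors
well inside the asserted bands.

## Known limitations

* The logistic-in-ratio psychometric and linear interpolation are
  reasonable but unverifiable choices; both are isolated behind
  `fit_psychometric()` / `estimate_indifference_profile()`.
* The repetition index inherits the asymmetry of the design (targets at
  r\* but distances uniform on 1–12 while bias distances are
  feasibility-restricted), so its absolute size depends on the discounting
  profile, not only on $\tau$.
* `rm_anova()` handles one or two within-subject factors on complete
  balanced data only — exactly what the preregistered analyses need,
  nothing more.
* The agent's decision-time distribution is right-skewed like human data
  but its tail behavior has not been matched to any empirical
  distribution.
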