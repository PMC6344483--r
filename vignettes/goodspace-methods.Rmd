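---
title: "Methods: choice models and encoding analysis under variable action costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choice models and encoding analysis under variable action costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goodspace)
```

# The scientific setting

`goodspace` implements, end to end, the analysis of a two-juice choice task
in which the two offers carry different saccadic action costs (a short,
cheap saccade vs a long, expensive one), and the presentation of the offers
is dissociated in time and space from the presentation of the saccade
targets. The question the analysis is built to answer is *where* the
decision is made: if neurons encoding the binary choice outcome do so
before the saccade targets appear — i.e., before any action plan can exist
— the decision must be computed in a non-spatial representation ("goods
space") rather than in action space.

Because the recordings that motivated this analysis are not publicly
deposited, the package pairs every analysis stage with a synthetic-data
generator that produces sessions and spike trains with known ground truth.
All quantitative claims made by the test suite are claims about recovery
and calibration on these synthetic cohorts, not about any real dataset.

# The behavioral model

On each trial the animal chooses between `#A` units of juice A and `#B`
units of juice B, one offered at low and one at high action cost. Choices
are modeled with a logistic regression on the log odds of choosing B:

$$
X = a_0\,\#B - a_1\,\#A
  + a_2(\delta_{B,+} - \delta_{A,+})
  + a_3(\delta_{n-1,B} - \delta_{n-1,A})
  + a_4(\delta_{\text{cost }B = \text{cost }n-1} - \delta_{\text{cost }A = \text{cost }n-1})
  + a_5(\delta_{B,\text{left}} - \delta_{A,\text{left}})
  + a_6(\delta_{\text{target }B,\text{left}} - \delta_{\text{target }A,\text{left}})
$$

with $P(\text{choose B}) = 1/(1+e^{-X})$. Each indicator
$\delta \in \{0,1\}$; all previous-trial indicators are 0 on the first
trial. Dividing by the value sensitivity $a_0$ expresses every effect in
units of juice B:

| index | definition | meaning | unit |
|---|---|---|---|
| $\rho$ | $a_1/a_0$ | relative value of A | units of B per unit of A |
| $\xi$  | $a_2/a_0$ | action-cost penalty of the long saccade | units of B |
| $\eta$ | $a_3/a_0$ | choice hysteresis toward the previously chosen juice | units of B |
| $\varphi$ | $a_4/a_0$ | hysteresis toward the previously chosen cost level | units of B |
| $\delta$ | $a_5/a_0$ | offer-side bias | units of B |
| $\varepsilon$ | $a_6/a_0$ | target-side bias | units of B |

Estimation is unpenalized maximum likelihood (`glm`) with Wald standard
errors. Two numerical escapes matter in practice:

* **Separation.** Deterministic choosers (large $a_0$, common in synthetic
  limit cases) separate the data; the fit falls back to a lightly
  ridge-penalized likelihood ($\lambda = 10^{-3}$) and is flagged.
* **Degeneracy.** The indices are ratios with denominator $a_0$; fits with
  $a_0 < 0.05$ (no detectable value sensitivity) report all indices as
  `NA` and are flagged degenerate.

A useful exact property (used as a regression test): relabeling the juices
swaps $a_0$ and $a_1$ in the same likelihood, so $\hat\rho \mapsto
1/\hat\rho$ and every value-unit index is divided by $\hat\rho$ — the
indices are re-expressed in units of the other juice, not invariant.

Sessions in which the target-side bias is significant (Wald $p(a_6) <
0.01$) are excluded from the neuronal analyses: an unexplained side
preference acts as an uncontrolled action cost and confounds the question
of interest. The per-configuration indifference point of the simplified
model (terms $a_3\ldots a_6$ removed) is $\rho + \xi$ when A is the
low-cost offer and $\rho - \xi$ when A is the high-cost offer, so the
A-low-cost sigmoid sits at higher `#B:#A` ratios exactly when $\xi > 0$.

# The synthetic task and its defaults

The generator's defaults are the package's reference study conditions and
are used unchanged throughout the tests:

* **Offer menu**: quantity pairs spanning `#B:#A` ratios 1:3 to 4:1 (six
  pairs; forced choices excluded). Quantities are uniform over the menu —
  the task description says only that they varied pseudo-randomly.
* **Counterbalancing**: each (pair × cost configuration × offer side) cell
  receives the same number of trials (default 83, i.e. 1992 trials, the
  closest counterbalanced design to a 2000-trial session), and the whole
  sequence is shuffled. Target angles are drawn uniformly from the four
  task angles with the two targets always in opposite hemifields.
* **Behavioral indices**: $a_0 = 2$, $\rho = 2.5$, $\xi = 0.25$,
  $\eta = 0.2$, $\varphi = \delta = \varepsilon = 0$. The hysteresis terms
  are simulated *causally* — trial $t$ uses trial $t-1$'s realized choice —
  so $\eta$ is genuinely recoverable.
* **Timing**: fixation 1.5 s; offers on 1 s; memory delay 1 s; target-to-go
  delay uniform in 0.6–1.2 s; a fixed 0.2 s saccade latency (reaction times
  are not part of the model); juice 0.75 s after the saccade. Trial time
  origin is fixation onset.

Neurons are Poisson. A neuron fires at its baseline everywhere; within its
tuned windows the rate is $\max(0, b + s\,v(\text{trial}))$ for encoded
variable $v$. The floor is truncation, not resampling, which slightly
biases strong negative tunings — negligible at the default signal strengths
(the signal never exceeds the 10 spikes/s baseline at SNR 2). Signal
strength is parameterized as $\mathrm{SNR} = s\cdot\mathrm{range}(v) /
\sqrt{b}$. Spike generation is exact (superposition above baseline,
thinning below), reported at 0.1 ms resolution. Because the go delay is
jittered, the post-target and pre-go windows can overlap on short-delay
trials; tuning contributions combine there.

What the generator deliberately does **not** emulate: non-Poisson
variability, rate adaptation, trial-history firing effects, correlated
noise across neurons, and error/aborted trials (only completed trials are
stored). Passing tests therefore demonstrate correctness and calibration of
the *analysis*, not robustness to these real-data features.

# Response screening

A *response* is one neuron in one of nine 0.5 s task-aligned windows
(pre-offer through post-juice; all intervals half-open `[start, end)` so a
boundary spike is counted exactly once). Rates are counts divided by window
duration. Each response enters two three-way ANOVAs — (trial type × offer A
location × target A location) and (trial type × chosen offer location ×
chosen target location) — at $p < 0.001$; a response significant for at
least one factor is task-related.

Choices that had to be made where the source analysis is silent:

* **Main effects only**, since only factor columns are tallied; interaction
  terms would change the residual df.
* **Trial-type levels** are the observed (offer type, chosen juice) tuples;
  levels with fewer than two trials are dropped.
* **Type II tests on rates**: each factor is tested by the F ratio of its
  marginal sum of squares (full main-effects model vs the model without
  that factor). The trial-type factor is shared between the two ANOVAs and
  computed once.

The screen is implemented as matrix algebra on precomputed QR
decompositions (the design is identical for all responses of a session), so
screening hundreds of neurons takes seconds. Under the untuned null the
per-factor false-positive rate sits inside the binomial band around 0.001
(calibration is part of the test suite).

# The variable catalog and selection

Nineteen candidate variables span four reference frames — commodity (offer
value A/B, chosen juice), cost (offer value −/+, chosen cost), visual
(offer value L/R, chosen location), action (offer value target L/R, chosen
target) — plus the cross-frame association variables and *chosen value*.
Value variables are in units of juice B and built from the session's own
behavioral fit: offer value A $= \hat\rho\,\#A + \hat\xi\,\delta_{A,+}$,
offer value B $= \#B + \hat\xi\,\delta_{B,+}$.

Each task-related response is regressed on each variable **at the
trial-type level** (mean rate per trial type against the variable's mean
value per trial type): a response is defined as activity as a function of
the trial type, and trial-level regression is retained only as an option.
A variable *explains* a response if its slope differs from zero at
$p < 0.05$; otherwise its effective $R^2$ is set to 0. Offer-value pairs
are collapsed into families credited with the larger component $R^2$; the
family with the largest effective $R^2$ is the response's *best fit*.

Two procedures then pick the encoded variables per epoch (pre-target =
post-offer…pre-target; post-target = post-target…post-juice; the pre-offer
window is baseline and belongs to neither):

* **Stepwise**: select the family with the most best fits within any single
  window; remove the responses it accounts for; repeat until the marginal
  explanatory power (newly accounted responses / all task-related responses
  in the epoch) falls below 5%. Ties break by total best fits, then catalog
  order — fully deterministic.
* **Best subset**: for each size $n$, the subset maximizing the number of
  responses explained by at least one member (ties by summed best member
  $R^2$, then catalog order), guaranteed optimal by exhaustive enumeration
  over the 15 families.

Two open design points were resolved by implementation evidence:

* **Removal rule.** Removing every response the selected family *explains*
  ($p<0.05$) lets the first value family absorb its near-collinear
  siblings: on synthetic cohorts, offer value (juice) explains essentially
  all chosen-value responses at the trial-type level, so chosen value can
  never be selected no matter how many neurons encode it. The default
  therefore removes only the responses the family best-fits
  (`removal = "best_fit"`), with the explained-removal rule switchable.
* **Best-subset set size.** The procedures are compared at the
  stepwise-matched subset size (with the marginal-gain stop rule available
  when no size is given). On the reference recovery cohort the two
  procedures then select identical pre-target sets containing all four
  generating families.

Cells are classified by the selected family with the largest summed
effective $R^2$ over all nine windows of their task-related responses. For
*chosen juice* cells the encoded juice E (the one eliciting higher rates)
is the sign of the chosen-juice slope, $R^2$-weighted across windows;
*chosen cost* cells get the analogous preferred cost level.

# Choice signals before target presentation

A quantity pair is **cost-overt** when choices track the cost assignment:
the fraction of A choices with A low-cost exceeds the fraction with A
high-cost by more than 10%, conditioned on each option being chosen at
least twice (pooled over the two configurations). A pair in which the same
option is chosen on every trial is **cost-covert** regardless of counts —
the strict at-least-twice reading would make consistently-dominated pairs
unlabelable, contradicting their role as the canonical covert example — as
is a pair shifting by at most 10% with both options chosen at least twice.
The remainder (one configuration missing, or a shift that cannot be
certified because one option was chosen fewer than twice) is
*insufficient*.

Choice probability is the ROC area under the curve between the spike-count
distributions of the two choice outcomes (E vs O for chosen-juice cells,
low- vs high-cost choice for chosen-cost cells), computed on **raw counts**
in three non-overlapping windows after offer onset (0–250, 250–500,
500–750 ms), within each cost-overt pair, ties counted half, then averaged
across eligible pairs. It equals the Mann–Whitney U statistic divided by
$n_1 n_2$ (asserted as a property test). The population test is a t test
of per-cell mean AUC against 0.5; it is reported two-sided, with direction
read from the mean (a constant vector at 0.5 yields $p = 1$ by
convention).

Activity profiles convolve 1 ms-resolution spike times with a Gaussian
kernel. "40 ms width" is interpreted as $\sigma = 40$ ms (not FWHM); the
parameter is exposed. The kernel is truncated at the grid edges without
renormalization, so profile mass equals the spike count up to edge effects.
Normalization subtracts the cell's mean pre-offer rate and divides by its
mean rate across the other eight windows; cells with a non-positive divisor
are excluded from population averages. Four-way trial grouping (E/O ×
overt/covert) requires at least two trials per group.

# Dimensional integration

Whether a value signal integrates the action cost (or, for cost-frame
values, the juice type) is tested by comparing two variants of its
variable: the *affected* variant is the full definition; the *independent*
variant removes exactly the determinant under test ($\hat\xi$ term dropped,
or $\hat\rho$ set to 1 — for offer value −/+ the $\hat\xi$ term is constant
within the variable, so raw quantity is the commodity-independent variant
either way). Because the variants are nearly collinear, identification must
not favor either: each response is credited with the **maximum** $R^2$ over
the two variants, re-assigned to selected families by best fit under that
rule, and restricted to the post-offer window (offer-value families) or
post-offer and post-target (chosen value). The per-response contrast is
$\Delta R^2 = R^2_{\text{affected}} - R^2_{\text{independent}}$ on the raw
$R^2$ of the winning component, summarized by its mean and a two-sided
Wilcoxon signed-rank test; the early/late chosen-value contrast uses a
rank-sum test between the post-offer and post-target populations. The
chosen-value cost-affected variant composes the cost-affected offer values
(the alternative — adding $\hat\xi$ for the chosen offer's low-cost flag
directly — is the same quantity).

The parallel-model ANCOVA (`rates ~ value + group`, single slope,
group-specific intercepts, F test on the group factor) complements
$\Delta R^2$; with a single group it reduces exactly to the simple
regression.

# Problem sizes, power, and runtime choices

The test suite fixes these simulation sizes as its study conditions:

* Behavioral recovery: 50 replicate sessions of 1992 trials. Median index
  bias is below 0.03 and the null indices' signed-rank tests stay above
  $p = 0.05$.
* Screen calibration: 200 untuned neurons × 9 windows on a 720-trial
  session (session length only affects power, which is irrelevant under
  the null).
* Label recovery: the reference cohort — 10 neurons each for offer value A,
  offer value −, chosen value, chosen juice at SNR 2 plus 10 untuned, 10
  spikes/s baseline, on a 1992-trial session.
* $\Delta R^2$ cohorts: 30 chosen-value neurons on 1992-trial sessions. The
  never/always cohorts use SNR 2. The early/late dissociation cohort uses
  SNR 4: a power analysis at these conditions shows the per-response
  $\Delta R^2$ noise (sd ≈ 0.015 at SNR 2) leaves the two-sample rank-sum
  contrast near 35% power at ~30 responses per epoch, while SNR 4 puts it
  above 90%. A designed demonstration of the dissociation must be powered
  for the test it feeds; the population-level never/always claims do not
  need the boost and keep SNR 2.

End-to-end, the default test suite runs in under two minutes on one CPU;
the acceptance script (20 replicate sessions plus one full cohort pipeline)
in about half a minute.

# Known limitations

* The trial-type-level regression makes spatial-frame value variables
  nearly degenerate (side assignments average out within trial types);
  they remain in the catalog because the ANOVA factors carry the spatial
  tests, and trial-level regression is available.
* The explained-removal stepwise rule is kept only as an option (see
  above); with it, selections on strongly tuned cohorts collapse onto the
  first value family selected.
* $\Delta R^2$ for cost-frame families contrasts $\hat\rho$-weighted vs
  raw-quantity values; when the generating $\rho$ is far from 1 this
  contrast is large, unlike the subtle $\hat\xi$ contrasts.
* The SDF edge truncation biases profile tails within half a kernel width
  of the trial boundaries; population conclusions use windowed counts, not
  profile tails.
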