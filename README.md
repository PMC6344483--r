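# goodspace

Analysis of economic choices under variable action costs, and of the
neuronal value signals recorded while those choices are made.

When a monkey chooses between two juices offered in different amounts, and
obtaining each offer requires a saccade of a different amplitude (a cheap
short one vs a costly long one), the decision necessarily takes some aspect
of the action into account. Are such decisions computed in a spatial,
action-based representation — or can the action cost be folded into a
non-spatial value and the decision made in "goods space"? The decisive
neural signature is timing: if orbitofrontal neurons encode the *binary
choice outcome* before the saccade targets are even shown, the comparison
must have happened before any action plan existed.

`goodspace` implements the full analysis pipeline behind that question as a
tested R package, together with a synthetic-data generator that produces
sessions and spike trains with known ground truth, so every stage can be
validated by parameter recovery and null calibration:

1. **Behavior** — a logistic choice model with action-cost, hysteresis and
   spatial-bias terms. The log odds of choosing juice B are

   *X* = a₀·#B − a₁·#A + a₂(δ_B,+ − δ_A,+) + a₃(δ_{n−1,B} − δ_{n−1,A})
   + a₄(δ_cost B = prev − δ_cost A = prev) + a₅(δ_B,left − δ_A,left)
   + a₆(δ_target B,left − δ_target A,left),

   giving normalized indices ρ = a₁/a₀ (relative value), ξ = a₂/a₀ (action
   cost), η (choice hysteresis), φ (cost hysteresis), δ, ε (spatial
   biases), all in units of juice B. Sessions with a significant
   target-side bias (ε) are screened out.
2. **Task-related responses** — spike counts of each neuron in nine
   task-aligned 0.5 s windows, screened with two three-way ANOVAs (trial
   type × offer A location × target A location; trial type × chosen offer
   location × chosen target location) at p < 0.001.
3. **Variable selection** — 19 candidate variables in four reference frames
   (commodity, cost, visual, action), regressed per response at the
   trial-type level, collapsed into families, and selected per epoch by
   deterministic stepwise and exhaustive best-subset procedures; cells are
   classified by their dominant variable.
4. **Choice probability** — ROC analysis of raw spike counts on cost-overt
   offer types in three post-offer windows: the probability an ideal
   observer infers the upcoming choice from one cell's activity, tested
   against 0.5 across the population.
5. **Dimensional integration** — ΔR² contrasts between cost-affected and
   cost-independent (or commodity-affected/-independent) variants of each
   value variable, identified without variant bias, plus a parallel-model
   ANCOVA.

## A worked example

Simulate a counterbalanced ~2000-trial session with the default study
conditions (a₀ = 2, ρ = 2.5, ξ = 0.25, η = 0.2) and fit the choice model:

```r
library(goodspace)
cfg <- generator_config(seed = 42)
s   <- generate_session(cfg)
fit <- fit_choice_model(s)
print(fit)
#> <gs_logistic_fit> n = 1992
#>          a0     a1     a2     a3     a4     a5     a6
#> coef 1.9463 4.9373 0.5238 0.3992 0.0217 0.0032 0.0497
#> se   0.0981 0.2611 0.0817 0.0843 0.0788 0.0784 0.0786
#> p    0.0000 0.0000 0.0000 0.0000 0.7826 0.9671 0.5270
#> indices:
#>     rho      xi     eta     phi   delta epsilon
#>  2.5368  0.2691  0.2051  0.0112  0.0017  0.0256
```

The fit recovers the generating indices: one unit of juice A is worth
ρ̂ ≈ 2.54 units of B; the long saccade costs ξ̂ ≈ 0.27 units of B; the
animal repeats the previously chosen juice as if it were worth η̂ ≈ 0.21
extra units; the null indices (φ, δ, ε) are small and non-significant, so
the session is kept:

```r
screen_session(fit)$keep
#> [1] TRUE
round(summarize_choice_pattern(s)$indifference, 2)
#>  A_low A_high
#>   2.87   2.33
```

The indifference point (the #B:#A ratio at which the animal is indifferent)
is higher when A is the low-cost offer — the behavioral signature of a
positive action cost.

## The full analysis

The `analysis/` directory holds the staged workflow, each script a thin
driver over the package:

```sh
Rscript analysis/01_simulate.R        # session + 50-neuron labeled cohort
Rscript analysis/02_fit_behavior.R    # choice model, screen, index recovery
Rscript analysis/03_screen.R          # response matrix + ANOVA screen
Rscript analysis/04_select.R          # variable selection + classification
Rscript analysis/05_choice_signal.R   # cost-overt ROC choice probability
Rscript analysis/06_integration.R     # delta-R2 integration tests
```

Outputs (CSV/JSON) accumulate under `results/`. On the bundled cohort the
pre-target stepwise and best-subset procedures select identical variable
sets — offer value (juice), offer value (cost), chosen value, chosen juice
— and 100% of tuned neurons are classified to their generating family;
chosen-juice cells predict the upcoming choice (mean AUC ≈ 0.77,
p < 1e−7) within 250 ms of offer onset, long before target presentation.

See `vignettes/goodspace-methods.Rmd` for the model details, the numerical
choices, and what the synthetic cohorts do and do not establish.

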