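# bibswarm

Self-propelled particle (SPP) swarms whose agents decide how far to
deviate from local velocity matching by **Bayesian and inverse Bayesian
inference**, plus the full analysis stack for asking whether the
resulting movement is a **Lévy walk**.

## Who this is for

Researchers in collective animal behavior and movement ecology who want a
tested, scriptable implementation of three nested swarm models and of the
standard Lévy-walk detection protocol (bending-angle step segmentation,
truncated power-law vs exponential maximum likelihood, KS-selected lower
cutoff, Akaike-weight model selection).

## The models

All agents move at constant speed `V = 5` per step and align with the
mean heading of neighbors within radius `R = 20`, plus angular noise
drawn uniformly from `[-epsilon, epsilon]`. Each agent carries a data
symbol `d` in `{0,1,2,3}` that offsets its heading by `d * pi/2`:

* **SPP** — `d = 0` always (pure Vicsek-type alignment).
* **BO** — `d` is sampled each step via Bayesian inference over four
  hypotheses `h`, each a fixed likelihood row `P(d|h)` (0.7 on the
  diagonal, 0.1 off); the posterior `P(h|d)` becomes the next prior.
* **BIB** — BO plus inverse Bayesian inference: each step the likelihood
  row of a preferentially *low*-probability hypothesis is overwritten by
  the empirical frequency of the agent's last `m` symbols,
  `P(d|f) <- P_window(d)`.

Step lengths are distances between consecutive bending points (turns
exceeding `alpha_max = 2*pi/9`). The headline result the package
reproduces: pooled BIB step lengths follow a truncated power law
`f(x) ∝ x^-mu` with `mu ≈ 2.5-2.8` and Akaike weight `w_pl = 1.00`
across noise levels and window sizes (a Lévy walk), while SPP and BO
remain exponential (`w_pl ≈ 0`, exponent pinned at a search bound).

## A worked example

```r
library(bibswarm)
fit <- run_levy_experiment("BIB", epsilon = 0.1, n = 300, steps = 3000,
                           seed = 1)
fit
#> Step-length model selection (truncated power law vs exponential)
#>   n = 707819 (tail n = 7547), xmin = 19.99, xmax = 978.4
#>   truncated power law: mu = 2.521, logLik = -31729.04, AIC = 63460.09
#>   exponential:     lambda = 0.0312, logLik = -33720.88, AIC = 67443.76
#>   Akaike weight of the power law: w_pl = 1.0000 -> Levy-walk-like (power-law preferred)
```

Reading: 300 BIB agents walked 3000 steps from a small central cluster in
open space; their pooled trajectories yielded 707,819 steps; the
KS-selected cutoff is about 20 length units (4 body lengths), and above
it the truncated power law with exponent `mu = 2.52` beats the
exponential decisively (`w_pl = 1`) — the Lévy-walk signature. The same
call with `model = "BO"` returns `mu = 3.00, w_pl = 0.00`: Bayes alone
does not produce it.

Other entry points: `simulate_swarm()` / `swarm_config()` for raw
trajectories (a classed object with `print`/`plot`/`as.data.frame`
methods), `pool_steps()` for step tables, `levy_fit()` for the model
selection on any step-length vector (with `print`, `summary`, `coef`,
`logLik`, `plot` methods), `index_series()` / `ratio_summary()` /
`compare_models()` for tornado/splash/translation behavior counts, and a
command-line interface (`inst/scripts/bibswarm`) with subcommands
`simulate`, `steps`, `fit`, `indexes`, `compare`.

The methods vignette (`vignettes/bibswarm-methods.Rmd`) documents the
model semantics, the two stabilization parameters the inference dynamics
require (`prior_leak`, `response_floor`), and all numerical choices in
the fitting protocol.

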