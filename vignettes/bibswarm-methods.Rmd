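---
title: "Swarms with Bayesian and inverse Bayesian inference: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarms with Bayesian and inverse Bayesian inference: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(bibswarm)
```

# The scientific question

Animal collectives — bird flocks, fish schools, insect swarms — often move
in ways statistically indistinguishable from a critical state: their
individual trajectories show Lévy-walk step-length distributions (power
laws with exponent $1 \le \mu \le 3$), and the group exhibits coexisting
ordered and disordered behavioral modes. Classical self-propelled-particle
(SPP) models only reach such a state at a finely tuned noise level. This
package implements and analyses a family of SPP models in which each
agent's deviation from local velocity matching is chosen by an internal
inference process, and asks when the resulting movement is Lévy-like
*without* parameter tuning.

Three nested models share the same kinematics:

* **SPP** — pure velocity matching plus angular noise.
* **BO** (Bayes only) — the agent holds four hypotheses $h \in \{0,1,2,3\}$
  about the swarm state, each defined by a fixed likelihood row
  $P(d \mid h)$ over four data symbols $d \in \{0,1,2,3\}$; every step it
  updates its belief by Bayes' rule, samples a hypothesis from the
  posterior, and samples its next symbol $d$ from that hypothesis's row.
* **BIB** — BO plus *inverse Bayesian* inference: each step, the
  likelihood row of a preferentially **low**-probability hypothesis is
  overwritten wholesale by the empirical frequency of the agent's own
  recent symbols (a FIFO window of size $m$). Bayes contracts beliefs onto
  the data; inverse Bayes re-seeds discredited hypotheses with the data's
  current empirical distribution.

The symbol $d$ acts on movement as a quarter-turn offset: the agent moves
at angle $\theta + s\,u + d\,\pi/2$, where $\theta$ is the mean heading of
its neighborhood (radius $R = 20$), $u \sim \mathrm{Uniform}[0,
\varepsilon]$ with a fair sign $s$, and the speed is fixed at $V = 5$ per
step. $d = 0$ means "conform"; $d = 2$ means "flee through the flock".

# Kinematics and simulation semantics

The update is synchronous. At each step, every agent's heading is the
two-argument arctangent of the summed displacement of its neighbors
(itself always included) between the two previous configurations;
neighborhoods are determined from the previous positions, with
minimum-image distances under a periodic boundary. All agents then move
distance $V$ exactly. Positions are stored unwrapped, so later geometric
analysis is never corrupted by wrap jumps. Degenerate cases are resolved
explicitly: a zero summed displacement keeps the previous heading
(a measure-zero event), and the first step uses a virtual previous
position one body-length behind each agent along a random initial heading.

Two scenario presets mirror the two analyses: `indexes` (periodic box of
side $L = 500$, uniform initial placement — the side length is not fixed
by the source models, and density does matter for collective structure)
and `levy` (open space, all agents started in a central square of side
50, run for $T = 10000$ at full scale).

# The inference dynamics, and why two regularization parameters exist

The per-step order is: Bayes update with the current symbol; posterior
becomes the new prior; (BIB) push the symbol into the window, select the
replacement target $f$ by inverse roulette (probability $(1 - P(h))/3$),
overwrite row $f$ with the window frequency; sample $h'$ from the
posterior; sample $d'$ from row $h'$.

Implemented literally, this system collapses — instrumented runs show two
distinct pathologies, both destroying the very dynamics the model is
meant to exhibit:

1. **Freeze.** Window frequencies routinely contain exact zeros (a window
   of size 10 usually misses at least one of four symbols). A zero
   likelihood entry multiplies a hypothesis's prior mass to exactly zero
   — permanently, since mass can only be rescaled thereafter; double
   underflow has the same effect more slowly. Once the posterior is a
   point mass on some $h_0$, the inverse roulette (which favors
   *low*-probability hypotheses) never selects $h_0$ again, so the one
   row that generates the data is never replaced. The symbol stream
   becomes i.i.d. from a frozen row: geometric run lengths, exponential
   step tails — behaviorally indistinguishable from BO.
2. **Absorption.** If a single symbol fills the window, every replacement
   writes a pure row; once all rows are pure the symbol can never change
   again, and the agent is ballistic (or loops) forever.

Neither state admits the perpetual likelihood turnover that defines
inverse Bayesian inference, so the model carries two explicit, documented
stabilizers, both defaulting to the round weak value $0.01$:

* `prior_leak` ($\gamma$): after each Bayes update the posterior is mixed
  with the uniform distribution, $(1-\gamma)\,P + \gamma/4$. Every
  hypothesis stays recoverable and the inverse roulette reaches every row
  with rate at least $\gamma/12$ per step. This is a standard forgetting
  term: a memory of unbounded depth is replaced by one of depth
  $\sim 1/\gamma$ steps.
* `response_floor` ($\delta$): when the next symbol is sampled from a
  likelihood row, the row is floored at $\delta$ per symbol and
  renormalized (sampling only; the stored table is untouched, so the
  likelihood replacement semantics remain exact). This keeps the symbol
  chain ergodic — pure rows are no longer absorbing — and reads
  behaviorally as a minimum response probability.

With these in place the dynamics do what the model intends: likelihood
rows turn over perpetually, symbol runs acquire a heavy-tailed length
distribution (reinforcement through the window acts like a lagged urn,
while the posterior competition supplies escapes), and the pooled
step-length distribution of a swarm becomes a truncated power law with
$\mu \approx 2.5$–$2.8$ over a broad range of $\varepsilon$ and $m$ (the
test suite verifies this signature at seven conditions). The defaults
were fixed once, on the qualitative requirement alone — perpetual
turnover without absorption — not against any fitted exponent; both
parameters are ordinary arguments, so the sensitivity of $\mu$ to them
is a one-line experiment for the reader.
Setting both parameters to zero reproduces the literal-collapse
phenotypes described above, which is itself instructive: the *contrast*
between BO and BIB — not the regularizers, which are shared by both — is
what produces the Lévy walk. Under identical $\gamma$ and $\delta$, BO
remains exponential ($\mu$ pinned at 3, $w_{pl} = 0$) because its frozen
diagonal likelihood cannot sustain long runs, while BIB's window
replacement can.

# Step geometry

A step ends where the bending angle — the arc cosine of the dot product
of successive displacements divided by $V^2$, clamped to $[-1, 1]$ —
strictly exceeds $\alpha_{\max} = 2\pi/9$. Step length is the Euclidean
distance between consecutive bending points; the track's first position
seeds the sequence and the incomplete trailing segment is discarded by
default (`emit_tail = TRUE` adds it; with the large step tables BO and
BIB produce, one extra segment per agent is negligible, and the flag
matters mainly for the step-starved noise-free SPP). Note a subtlety of this definition: steps can be *shorter* than
$V$, because a segment that curls around (many sub-threshold turns) can
end close to where it began. One-step walks contribute an atom at exactly
$V$; this atom dominates the pooled table (50–75% of all steps in BO/BIB
runs) and is a key numerical fact for the fitting protocol below.

# Lévy-walk detection

Two candidate densities are fitted to the pooled step lengths above a
lower cutoff: the hard-truncated power law
$f(x) = \frac{\mu - 1}{x_{\min}^{1-\mu} - x_{\max}^{1-\mu}} x^{-\mu}$ on
$[x_{\min}, x_{\max}]$, and the shifted exponential
$f(x) = \lambda e^{-\lambda (x - x_{\min})}$. $x_{\max}$ is the sample
maximum. (Movement-ecology work sometimes uses the softly truncated form
$f(D) \propto D^{-\mu} e^{aD}$ instead; it is noted here for orientation
but is not part of this fitting protocol, which uses the hard truncation
above.) $x_{\min}$ is selected by minimizing the Kolmogorov–Smirnov
distance between the empirical tail CDF and the fitted truncated power
law over candidate cutoffs; both models are then fitted to the same tail
and compared by AIC with one free parameter each, summarized as the
Akaike weight $w_{pl}$ of the power law.

Numerical choices, all visible as arguments:

* $\mu$ is maximized over $[1 + 10^{-6},\, 3]$ by bounded 1-D
  optimization with the interval endpoints checked explicitly, so
  misspecified data report exactly $1.00$ or $3.00$ (the Lévy exponent
  range treated as a prior constraint; both bounds are routinely hit by
  the control models).
* $\lambda$ has the closed form $1/(\bar{x} - x_{\min})$.
* Candidate cutoffs are unique data values up to the 99th percentile,
  thinned to at most 200 quantile-spaced values; ties in KS distance go
  to the smallest cutoff, and a candidate tail must retain at least 10
  points. The 99th-percentile cap (not, say, the 90th) is forced by the
  atom at $V$: in BO/BIB runs more than 90% of steps can sit at or below
  one body length, and a lower cap would trap the cutoff inside the atom
  where neither model fits — making the model decision a coin flip. With
  the cap above the atom the selected cutoff lands where the heavy tail
  begins, typically a few body lengths.
* The selection scan is $O(\text{candidates} \times n)$ using suffix
  sums of $\log x$, so fitting $7 \times 10^5$ pooled steps takes seconds.

# Behavior indexes

Three non-exclusive per-time-step counts summarize collective structure,
all based on a trailing window $W = 10$ of bending angles: **tornado**
(mean turn strictly between $\pi/30$ and $\pi/10$ — circling at radii of
roughly 8–48 length units at $V = 5$), **translation** (mean turn below
$\pi/30$), and **splash** (nearest-neighbor distance grew by more than
$r_{spl} = 8$ over the last $T_{spl} = 10$ steps, minimum-image under a
periodic boundary). Agents without full history are excluded rather than
padded; ratio series skip time steps with a zero translation count and
report the skip count. $W$ and $T_{spl}$ are configurable because the
source analysis does not pin them down; the summaries use the standard
six-number convention (minimum, quartiles, median, mean, maximum).

A candid limitation: under the reconstructed dynamics the *ratio*
comparisons between BIB and BO do not reproduce the published ordering.
The reason is mechanical. Index-qualifying turning requires gentle,
sustained curvature (6–18° per step), but in these models individual
turns are quantized at multiples of 90°: an agent that briefly samples a
non-zero symbol and returns produces two 90° turns in one window (mean
18°/step — exactly at the tornado band's open boundary), so BO agents
almost never qualify for either tornado or translation, and the
denominators of the published ratios are starved. Whatever produced
gentle per-step curvature in the original implementation is not
recoverable from the printed model. The machinery itself is fully tested
on constructed fixtures (circles, ballistic tracks, mixed populations,
brute-force nearest-neighbor oracles) and reproduces the qualitative SPP
phenotype (translation-dominated, near-zero splash).

# What the synthetic data can and cannot show

Everything here is simulation: the "data" are the models' own
trajectories, so passing tests demonstrate internal correctness and the
claimed *contrast between models*, not anything about real animals. The
trajectories lack measurement noise, irregular sampling, boundary effects
of real arenas, and body-size heterogeneity; the step-length analysis
consequently sees far cleaner power laws than field data ever provide.
The validation scale is $N = 300$ agents and $T = 3000$ steps (nine
conditions run in a few minutes on one core), with the full study scale
$N = 1000$, $T = 10000$ available through the same functions and the
same seeded determinism.

# Known limitations

* The two stabilization parameters are reconstructions; the printed
  equations alone are unstable (collapse or absorb), so some such choice
  is unavoidable, but other stabilizers (pseudocount smoothing of the
  window frequency, likelihood-floor variants) would give slightly
  different exponents. All are exposed as arguments.
* The periodic-box side, central-square side, index windows $W$ and
  $T_{spl}$, and the xmin candidate rule are not determined by the source
  models; defaults are stated above and threaded through all outputs.
* Hypothesis and data alphabets are fixed at four symbols.

# A worked example

```{r example, eval = FALSE}
library(bibswarm)
fit <- run_levy_experiment("BIB", epsilon = 0.1, n = 300, steps = 3000,
                           seed = 1)
fit
#> Step-length model selection (truncated power law vs exponential)
#>   n = 707819 (tail n = 7547), xmin = 19.99, xmax = 978.4
#>   truncated power law: mu = 2.521, logLik = -31729.04, AIC = 63460.09
#>   exponential:     lambda = 0.0312, logLik = -33720.88, AIC = 67443.76
#>   Akaike weight of the power law: w_pl = 1.0000 -> Levy-walk-like (power-law preferred)
plot(fit)
```

The same pipeline in shell form:

```sh
bibswarm simulate --model bib --n 300 --steps 3000 --epsilon 0.1 \
         --seed 1 --out traj.csv
bibswarm steps --in traj.csv --out steps.csv
bibswarm fit --in steps.csv --out fit.json --ccdf ccdf.csv
```
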