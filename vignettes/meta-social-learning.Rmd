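---
title: "Meta-control of individual and social learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-control of individual and social learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasl)
```

# The problem

A population of agents repeatedly faces a $k$-armed bandit whose reward
distributions change over time. Each agent can learn *individually*
(trial and error on its own value estimates) or *socially*, by copying
others: either the action of the single best-rewarded individual
(success-based copying) or the most frequent action in the population
(conformist copying). Individual learning pays an exploration cost;
social learning is cheap but can mislead — success-based copying in
particular fails when reward noise makes it hard to tell who is actually
successful. `metasl` implements the full modelling stack around this
trade-off: the environments, the learners, an uncertainty statistic
(ODPU), a context encoding, a family of meta-controllers that arbitrate
between the three strategies, a replicator–mutator ODE model, agent-based
evolutionary simulations, controller training, and the experiment
runners with their statistics.

# Models

## Individual learning

Each agent keeps per-arm value estimates updated by
$Q(a) \leftarrow Q(a) + \beta\,(r - Q(a))$ with step size $\beta = 0.2$,
and acts $\epsilon$-greedily with $\epsilon = 0.1$ (ties toward the
lowest arm index). Both constants are the study's settings and are
configurable through `evo_config()`. The same update serves as the
decision model of social learners, who also observe their own rewards.

## Social learning

Social learners read the shared record of the previous generation
(latency $\tau$, default 1 generation; the paper's source never needs
more than the previous step and the smallest lag keeps the information
as fresh as possible). Success-based learners copy the arm of the
individual with the single highest recorded reward; conformists copy
the most frequent arm. Ties break toward the lowest arm index. When no
record exists yet ($t - \tau \le 0$), agents fall back to individual
learning. Whether "best reward" means the best single individual or the
best arm-average is genuinely ambiguous in the source; we implement the
single best individual (the literal reading), which also produces the
uncertainty sensitivity the theory predicts — a population copying a
single lucky draw is exactly what the ODPU quantifies.

## The ODPU

The *optimum distribution prediction uncertainty* is the probability
that the maximum of the rewards drawn from sub-optimal distributions
exceeds the maximum drawn from the optimal one. For Gaussian groups
$(\mu_i, \sigma_i)$ with $N_i$ draws, the maximum of group $i$ has cdf
$\Phi\!\big(\tfrac{x-\mu_i}{\sigma_i}\big)^{N_i}$, and

$$\mathrm{ODPU} = 1 - \int f^{(1)}_{\max}(y)\ \prod_{i\ge 2}
F^{(i)}_{\max}(y)\, dy .$$

`odpu()` evaluates this after the substitution $u = F^{(1)}_{\max}(y)$,
i.e. in the quantile space of the optimal group's maximum. The
transformed integrand is bounded on $(0,1)$, so the quadrature remains
exact when some $\sigma$ sits at the $10^{-6}$ floor the context
encoding applies — the direct integrand degenerates into a spike there
and adaptive quadrature can miss it entirely. $\Phi^N$ is computed in
log space to avoid underflow at large $N$. `odpu_monte_carlo()` is the
independent simulation oracle used in the tests, and
`odpu_bernoulli()` covers the two-point reward variant in closed form.

## What "high uncertainty" means here

Low-uncertainty environments use means $(1.0, 0.5)$ with
$\sigma = (0.05, 0.05)$. For high uncertainty we use
$\sigma = (0.1, 0.4)$: a concentrated optimum and a heavy-tailed
sub-optimal arm, the configuration with near-maximal ODPU
($\mathrm{ODPU}(5, 95) \approx 0.99$). This asymmetry is essential, not
cosmetic: inflating *both* standard deviations equally does not make
success-based copying unreliable, because the optimum group's maximum
grows with its own $\sigma$ and keeps winning the max-comparison. Only
when the sub-optimal tail overhangs a tight optimum does the
best-observed reward regularly come from the wrong arm. The original
study's supplementary environment parameters are not printed, so these
values are this package's own operationalisation of its uncertainty
construct.

## Context encoding

Three bits summarise the social record at each step, from the
cross-sectional per-arm means $\mu'_j$, standard deviations
$\sigma'_j$ and frequencies $h(a_j)$:

* **EC** (environment change): $|\mu'_*(t) - \mu'_*(t-\delta)| >
  th_{EC}$ (strict), with $th_{EC} = 0.15$, $\delta = 1$ and the
  optimum re-evaluated each step. $\delta$ is not stated in the source;
  the smallest lag is the only one consistent with the formula without
  inventing structure.
* **C** (conformity): the best-estimated arm coincides with the most
  frequent arm, reset to 0 whenever EC fires.
* **U** (uncertainty): $\mathrm{ODPU}(\mu', \sigma', n) > th_u$ with
  $th_u = 0.1$; $\sigma'$ floored at $10^{-6}$, counts floored at 1.

Estimates are cross-sectional (this step's rewards only), so they reset
naturally after a change; an EMA variant was considered and rejected
because stale pre-change values would mask the new regime.

## Meta-controllers

All controllers map available information to
`{IL, SUCCESS, CONFORMIST}`:

* rule-based: EC-Conf, EC-Succ (alias EC-Unc — the source uses both
  names for the same controller), EC-Conf-Unc (conformity wins; else
  success under low uncertainty; else IL; any EC or the first step
  reverts to IL);
* `discrete_policy()`: an arbitrary table over the 8 context states
  plus the two thresholds — the 10-gene genotype optimised by
  `ga_optimize_policy()` ($3^8 = 6561$ distinct tables);
* `fcn_controller()`: a 6–12–3 feedforward network (bias units in
  input and hidden layers, 123 weights) on
  $(\mu'_1, \mu'_2, \sigma'_1, \sigma'_2, h_1, h_2)$, trained by
  `ne_optimize_fcn()` (GA or rand/1 differential evolution). The
  hidden activation is unstated in the source; we use tanh (bounded,
  standard for small evolved networks) with a linear argmax output;
* value-based: $\epsilon$-greedy and UCB over the three strategies
  (UCB constant $c = 1$, configurable; untried strategies first) and
  Q-learning over the 8 context states
  ($\epsilon_{QL} = 0.2$, $\alpha = 0.01$, $\gamma = 0$);
* fixed-probability baselines (IL-Only, uniform, 0.45/0.45/0.10,
  conformist-0.95, success-0.95).

Value-based controllers update on every step with the received reward
(not only on strategy switches); that is the standard bandit reading
and uses all available feedback.

## Replicator–mutator dynamics

`replicator_integrate()` evolves frequencies $(A_1, A_2, SL)$ under
$\dot{x}_k = F \cdot (x \circ M_{\cdot k}) - x_k \psi$ with
row-stochastic mutation matrix $M$ (off-diagonal rate 0.005 by
default) and average fitness $\psi = F \cdot x$. Payoffs are expected
rewards — the model is mean-field. Success-based social learners earn
the optimal payoff; conformists earn the payoff of the majority action
at lag $\tau$, tracked through a stored history of
$h(a_i,t) = A_i + SL \cdot H_{SL}(a_i,t)$, and earn nothing before any
history exists. Integration is fixed-step explicit Euler (default
$dt = 0.01$) with renormalisation when simplex drift exceeds
$10^{-9}$; the tests verify first-order convergence against step-halved
runs. Euler-with-history is used deliberately: the delayed, piecewise
constant right-hand side defeats off-the-shelf smooth ODE steppers.

## Agent-based evolution

`evolve_population()` (two types: IL plus one social strategy) and
`evolve_meta()` (each agent carries its own meta-controller) implement
the generational loop: act, collect the reward as fitness, record the
social information, select $m$ parents by roulette wheel
($p_i \propto f_i^s$), mutate types with rate $mr$ (default 0.005),
and track ages (first copy of a parent inherits its age, other copies
and mutants restart at 0, everyone then ages by 1). Offspring carry
their parent's decision model — the source's loop carries agents
across generations with no stated reset. Rewards can be negative under
wide Gaussian noise, so selection masses are shifted by
$\min(0, \min f)$ and floored at $10^{-9}$; the flooring never reorders
non-negative fitnesses. Selection-strength presets low/moderate/high
map to $s \in \{0.5, 1, 2\}$ (the source names the levels only).

## Training

`policy_fitness()` scores a candidate controller by the median over
seeded runs of $\sum_t \psi(t)$, with a shared seed list per optimiser
generation (common random numbers, to stop evaluation noise from
dominating selection). The policy GA uses 50 individuals, 4 elites,
one-point crossover at 0.8, per-discrete-gene mutation $1/8$,
Gaussian $\mathcal N(0, 0.1)$ threshold perturbation clipped to
$[0,1]$, stops after 20 stagnant generations (cap 200 — the source
states only the stagnation rule) and returns the best of 10 restarts.
Neuroevolution runs the same GA (5 elites) or DE
($F = 0.5$, $CR = 0.1$, rand/1, uniform crossover) on the 123-weight
genome initialised in $[-1, 1]$. `train_qlearning()` learns a shared
$8 \times 3$ table online inside an evolutionary simulation.

# Experiments and statistics

`run_fig2()` compares the three compositions (IL-only, success + IL,
conformist + IL) on low- and high-uncertainty reversal tasks, with the
post-change window $[200, 250]$ and end window $[350, 400]$ on the
$T = 400$ horizon. `run_fig3()` sweeps a $(\sigma_1, \sigma_2)$ grid,
pairing each cell's ODPU with the median end-window reward difference
(conformist minus success). The ODPU is evaluated at the measured
end-of-run occupancy (mean per-arm chooser counts over the end window
of the success runs, unrounded), so the statistic and the performance
it predicts refer to the same population state; the resulting value is
the per-generation probability that the best observed reward comes
from the wrong arm. Medians rather than means absorb the rare
finite-population runs ($m = 100$) in which a conformist majority
stays locked on the stale arm through the whole end window — at the
study's population scale those lock-ins do not occur, at desk scale
they would otherwise dominate the cell averages. `run_fig4()` and
`run_fig5()` run the meta-strategy benchmark and the evolutionary
competition. Statistics: two-sided Wilcoxon rank-sum tests
(`compare_strategies()`), Friedman average ranks with the Nemenyi
critical difference $CD = q_\alpha \sqrt{k(k+1)/(6N)}$
(`rank_and_cd()`, $q_\alpha$ from the studentized range), and the
exploration cost $\epsilon \times$ (number of individual-learning
agent-steps).

## Problem sizes

Desk-scale defaults are $m = 100$, $T = 400$, 30 runs per composition
for the reversal comparisons, and a $4 \times 4$ $\sigma$-grid at
$\{0.1, 0.2, 0.3, 0.4\}$ with 30 seeds per cell for the correlation
sweep; the competition default is $m = 500$ scale-equivalent settings
with 16 runs, and the original study scale ($m = 5000$, 112 runs) is
reachable through `evo_config()` and the runners' arguments or the
CLI's `--paper-scale` flag. `scripts/acceptance.R` reruns the three
headline quantities at the desk scale from a single seed.

# What the generator does and does not emulate

The synthetic environments reproduce the structural features the
models respond to: abrupt reversals, stable (2 changes) and volatile
(5 changes) schedules, randomised change schedules, gradual linear
drifts (window defaulting to half the horizon; the functional form of
"gradual" is unstated in the source, and linear interpolation of
$(\mu, \sigma)$ is the simplest choice), and Bernoulli rewards. They
do not emulate agent heterogeneity, observation networks, payoff
structures beyond two-point or Gaussian rewards, or any coupling
between agents' actions and the environment. Passing tests therefore
demonstrate the internal consistency of the models and their
qualitative ordering under these idealised conditions, not predictions
about any natural population.

# Known limitations

* At $m = 100$, absorbing-type finite-size events (a conformist
  majority locked on a stale arm) occur in a few percent of runs;
  medians and rank statistics are used where they would otherwise
  distort comparisons.
* The gradual-change environment defeats the threshold-based EC
  detectors by construction; this is the expected behaviour, not a
  defect.
* The ODE model is mean-field with a single delayed majority signal;
  it does not capture the value-learning transients of the agent-based
  loop, only the strategy-frequency dynamics.
* Training at the published scale (50-individual optimiser populations
  over full evolutionary simulations, 10 restarts) is computationally
  heavy; the defaults in the examples and tests use reduced settings,
  and the full settings are plain arguments.
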