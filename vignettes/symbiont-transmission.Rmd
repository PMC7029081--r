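---
title: "Modelling and estimating symbiont transmission in insect host populations"
author: "symbiodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and estimating symbiont transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiodyn)
```

## The scientific problem

Heritable bacterial symbionts of insects disperse along two routes:
vertically, from mother to offspring at birth, and horizontally, by contact
between hosts (for instance parasitoid-mediated "dirty needle" transfer).
Whether a symbiont persists in a host population, and whether two symbionts
can coexist within it, depends on the balance of these routes, on host
births and deaths, and — at larger scales — on host movement between
habitat patches. `symbiodyn` implements a hierarchy of SIR-type models for
these processes and the machinery to confront them with prevalence
time-series data: simulation (deterministic and stochastic), synthetic
experiment generation with observation error, Bayesian parameter
estimation, and formal model comparison.

## Model hierarchy

### Full metacommunity model

Hosts in patch $i$ of $J$ are susceptible ($S_i$), singly infected
($I_{Ai}$, $I_{Bi}$) or coinfected ($X_i$); $N_{it}$ is the patch total at
time $t$. Writing $\Lambda_A = \beta_A (I_{Ai} + q X_i)/N_{it}$ and
$\Lambda_B = \beta_B (I_{Bi} + q X_i)/N_{it}$ for the frequency-dependent
forces of infection,

$$
\begin{aligned}
S_i' &= \nu_b\left[\phi(X_i + I_{Ai} + I_{Bi}) + S_i\right] - \nu_d S_i
       - (\Lambda_A + \Lambda_B) S_i - m S_i + \textstyle\sum_{l \ne i} \rho_{i,l}\, m S_l \\
I_{Ai}' &= \nu_b (1-\phi)(c_A X_i + I_{Ai}) - \nu_d I_{Ai}
       + \Lambda_A S_i - \psi \Lambda_B I_{Ai} - m I_{Ai} + \textstyle\sum_{l \ne i} \rho_{i,l}\, m I_{Al} \\
I_{Bi}' &= \nu_b (1-\phi)(c_B X_i + I_{Bi}) - \nu_d I_{Bi}
       + \Lambda_B S_i - \psi \Lambda_A I_{Bi} - m I_{Bi} + \textstyle\sum_{l \ne i} \rho_{i,l}\, m I_{Bl} \\
X_i' &= \nu_b (1-\phi)\left[1 - (c_A + c_B)\right] X_i - \nu_d X_i
       + \psi \Lambda_B I_{Ai} + \psi \Lambda_A I_{Bi} - m X_i + \textstyle\sum_{l \ne i} \rho_{i,l}\, m X_l.
\end{aligned}
$$

Assumptions worth making explicit:

* infection affects neither the birth rate $\nu_b$ nor the death rate
  $\nu_d$ (no virulence or fecundity effects);
* every class reproduces; offspring of susceptible mothers are always
  susceptible, offspring of infected mothers are symbiont-free with
  probability $\phi$ and otherwise inherit the mother's infection, with the
  coinfected split $(c_A, c_B, 1-(c_A+c_B))$ conditional on transmitting.
  Under this reading total births are exactly $\nu_b N_{it}$, which is the
  property we test;
* coinfection is acquired sequentially, never in one contact; coinfected
  hosts transmit each of their symbionts with modifier $q$ and singly
  infected hosts acquire the other symbiont with susceptibility modifier
  $\psi$ (which multiplies the whole secondary-infection term);
* transmission is frequency dependent — forces of infection divide by the
  patch- and time-varying $N_{it}$; in an empty patch the force of
  infection is defined as 0;
* emigrants leave at per-capita rate $m$ and all land somewhere:
  $\rho$ is indexed `[destination, source]`, has zero diagonal and unit
  column sums. `build_migration_matrix()` derives $\rho$ from pairwise
  distances with an exponential kernel $\rho_{i,l} \propto
  e^{-d_{i,l}/\lambda}$ by default (a Gaussian kernel is available); the
  kernel family is a modelling choice, not a claim about any particular
  insect.

### Two-symbiont experiment model

Laboratory coinfection experiments run for a few weeks on closed
populations, so demography and migration are switched off. The remaining
four-parameter system (`experiment_rhs()`) conserves hosts exactly — the
four derivatives sum to zero for every state, which is enforced by a
property test over random states and parameters.

### Single-symbiont SI model

With one symbiont the system collapses to $I' = \beta I (N - I)/N$, whose
solution is the logistic curve
$I(t) = I_0 N / (I_0 + (N - I_0) e^{-\beta t})$. The closed form serves
two roles: an exact oracle for the numerical integrator (agreement to
$10^{-6}$ relative error across a $\beta \times N \times I_0$ grid is an
acceptance-level test) and the fast prediction path inside the
single-symbiont likelihood.

## Simulation

`integrate_model()` wraps an adaptive solver (`deSolve::lsoda`) with
`rtol = 1e-8`, `atol = 1e-10`; post-step negatives within tolerance are
clipped at zero. `gillespie_simulate()` is an exact direct-method
simulator on integer counts; its event set comprises, per patch, the four
horizontal-infection channels, births (the offspring class drawn at event
time from the mother class's vertical-transmission split), per-class
deaths, and per-class emigration routed by a categorical draw over
$\rho[, l]$. States are recorded on a user grid as the state just before
the first event after each grid time.

A caution learned from the exact master equation of the SI chain: the
mean-field ODE *over*-estimates the mean of the stochastic process once the
epidemic enters its nonlinear phase, because
$E[I(N-I)] = E[I]\,(N - E[I]) - \mathrm{Var}(I)$. At $N = 500$,
$\beta = 0.5$, $I_0 = 5$ the exact mean at $t = 10$ is 286.2 versus an ODE
value of 299.9 — a discrepancy of several Monte-Carlo standard errors at
a few thousand replicates. The simulator is therefore validated against
the master-equation mean (a pure-birth chain solved to $10^{-10}$), not
against the ODE.

## Synthetic experiments and observation error

`simulate_release_experiment()` emulates the canonical transmission-rate
assay: one infected host released into $N - 1$ susceptibles, three
replicate populations, sampled every 2 days, with the default
$\beta = 0.5$ day$^{-1}$ host$^{-1}$. Replicates share the deterministic
epidemic and differ only in observation noise, which is how the original
protocol describes its synthetic data. Choices the protocol leaves open,
fixed here once: the horizon is 20 days (the epidemic is essentially
complete at the default rate) and the assay is a full census
(`n_assayed = N`), both configurable.

`simulate_coinfection_experiment()` builds the four-population design with
initial conditions $(S_0, I_{A0}, I_{B0}, X_0)$ = (90, 0, 0, 10),
(90, 5, 5, 0), (88, 10, 0, 2), (88, 0, 10, 2) — varying the starting
conditions makes the transients differ and all four parameters estimable.
The sampling interval (2 days) mirrors the single-symbiont design. The
generating parameters are not part of the published design; the package
defaults $(\beta_A, \beta_B, q, \psi) = (0.5, 0.35, 0.75, 1.25)$ were
chosen once as a realistic asymmetric regime — unequal transmission rates,
mild interference in transmission from coinfected hosts ($q < 1$), mild
facilitation of secondary infection ($\psi > 1$) — and recovery is checked
by interval coverage, not by matching any published posterior.

Observation error: assaying $n$ hosts classifies each into one of
$\{S, I_A, I_B, X\}$, so `observe()` draws a single multinomial per
(replicate, time); each class count is then marginally binomial with index
$n$ and the model's class fraction as success probability, and the counts
are jointly consistent (they cannot exceed $n$). The single-class reduction
is an ordinary binomial draw. Every replicate consumes its own
deterministic seed substream, so replicate $k$ is unchanged by how many
replicates are requested.

## Inference

The likelihood multiplies binomial (one symbiont) or multinomial (two
symbionts) probabilities of the observed counts given model-predicted
class fractions at the observation times — fractions from the exact
logistic solution for the SI model and from a fresh ODE solve per proposal
for the two-symbiont model (all four populations stacked into one `lsoda`
call at `rtol = 1e-6`). Two numerical choices matter:

* ODE-predicted class probabilities are smoothed as
  $(p + \varepsilon)/(1 + 4\varepsilon)$ with $\varepsilon = 10^{-8}$,
  chosen well above the solver's absolute tolerance ($10^{-10}$). The
  experiment model's classes are strictly positive whenever dynamically
  reachable, so near-zero predictions are dominated by solver truncation
  noise; propagated raw into $k \log p$ that noise produces huge,
  discontinuous log-likelihood jumps (and exact zeros produce $-\infty$
  cliffs) that can freeze a random-walk sampler on low-likelihood
  plateaus, while the smoothing biases realistic probabilities by less
  than one part in $10^{6}$. The binomial SI path keeps exact zeros, which
  are structural there (an impossible datum yields a flagged $-\infty$).
* Priors default to half-Normal(0, 5) on every free parameter — the vague
  Normal(0, 5) truncated to the support, since negative rates are
  meaningless. Truncation of the original vague prior is a reading, not a
  documented fact, and the prior is configurable per parameter
  (`prior_spec()`).

Sampling is adaptive random-walk Metropolis on log-transformed parameters
(Jacobian included), not a gradient-based sampler: ODE gradients are out of
scope, and the contract is a correct posterior sampler, for which the
3-chain, 5,000-iteration, 2,000-warm-up, thin-3 default budget mirrors the
original fitting protocol. During warm-up the proposal scale chases the
dimension-appropriate acceptance rate (0.44 univariate, 0.234 multivariate)
by Robbins–Monro, and after a quarter of warm-up the proposal correlation
is refreshed every 50 iterations from the second half of the chain history
— using the full history lets the initial transient inflate the proposal
and was observed to stall chains. Chains initialise from prior draws
(re-drawn up to 50 times if the likelihood is non-finite); for
multi-parameter models each chain first runs a short Nelder–Mead mode
search from its prior draw and starts from the jittered optimum, because a
vague prior regularly lands chains in saturated regions of parameter space
that a finite warm-up cannot escape. A chain that still accepts under 2%
of post-warm-up proposals triggers a warning. Convergence is
monitored by split R-hat and Geyer initial-monotone-sequence effective
sample sizes; the release-experiment fit at defaults achieves split
R-hat < 1.05, which is asserted nowhere tighter than the tests themselves
verify.

Degenerate inputs behave predictably: data that constrain nothing (e.g.
observations only at $t = 0$) return the prior, all-zero counts produce a
proper posterior concentrated near zero transmission, and a proposal whose
ODE solve fails is treated as rejected ($-\infty$ likelihood with a logged
warning).

## Model comparison

`compare_models()` computes WAIC from the retained pointwise
log-likelihood matrices: $\widehat{\mathrm{elpd}} = \sum_i \log
\bar{p}_i - \sum_i V_i$, with standard errors from the pointwise spread
and pairwise-difference SEs from the paired pointwise differences. WAIC
was chosen because it needs only the pointwise matrix already stored on
every fit; the matrix is retained precisely so other criteria could be
added. Restricted model versions (e.g. $q = \psi = 1$: coinfected hosts
neither more nor less transmissible, no interference in secondary
infection) are built by moving parameters from `free` to `fixed` in
`model_spec()`, which is how the package phrases "which processes does the
data support" as a testable question.

## Problem sizes used in the checks

The shipped test suite and `scripts/acceptance.R` run the release
experiment at its native scale (3 replicates of 50 hosts, 11 sampling
times) with 20 independent seeds for interval coverage; the coinfection
design at its native scale (4 populations of 100) with 10 seeds at a
3-chain, 2,500-iteration budget, which already yields split R-hat near 1;
2,000 Gillespie replicates at $N = 500$ for the stochastic mean; and a
400-replicate master-equation comparison at $N = 60$. These sizes are the
package's chosen demonstration scale: large enough that coverage and
convergence are meaningful, small enough to re-run routinely.

## What the synthetic data do not show

The generators emulate the published simulation protocols: deterministic
dynamics plus sampling error, perfectly assayed infection status, no
assay misclassification, equal assay effort at every time, closed
populations, and replicates that differ only through observation noise.
Passing recovery tests on such data demonstrates the estimator is
self-consistent — it says nothing about model misspecification in real
systems (demographic stochasticity in small experimental populations,
symbiont loss, density- rather than frequency-dependent contact, host
heterogeneity). The stochastic simulator exists partly to probe the first
of these gaps: fitting the deterministic likelihood to Gillespie output is
the natural in-package misspecification experiment.

## Known limitations

* The full $J$-patch metacommunity model is supported for simulation
  (deterministic and stochastic) and its likelihood machinery is
  deliberately not wired to field data — estimating migration from
  prevalence series alone is weakly identified and belongs to
  mark–recapture designs.
* The sampler is a random-walk method: posteriors with strong curved
  ridges (e.g. $q$ against $\psi$ under sparse assays) mix slowly, which
  is why the default budget retains 3,000 draws and diagnostics are
  attached to every fit rather than left to the user's discipline.
* WAIC assumes pointwise observations are conditionally independent given
  parameters; with strong overdispersion a leave-one-replicate-out scheme
  would be more defensible.
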