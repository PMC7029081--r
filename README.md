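# symbiodyn

Transmission dynamics and Bayesian inference for heritable bacterial
symbionts in insect host populations.

Many insects carry facultative bacterial symbionts (*Wolbachia*,
*Hamiltonella*, *Spiroplasma*, ...) that pass both vertically, from mother
to offspring, and horizontally, between hosts. Understanding which of these
transmission routes — together with host demography and movement between
habitat patches — structures symbiont communities requires fitting
mechanistic transmission models to prevalence time series from laboratory
release experiments or field surveys. `symbiodyn` provides the full
tool-chain for that workflow: the coupled ODE models, an exact stochastic
simulator, generators for synthetic experiments with observation error,
posterior inference for the transmission parameters, and formal model
comparison.

## The models

Hosts in patch *i* are susceptible (*S*), singly infected with symbiont A or
B (*I_A*, *I_B*), or coinfected (*X*). The full metacommunity model couples
three processes per patch:

* **Demography and vertical transmission** — all hosts reproduce at rate
  ν_b and die at rate ν_d. A birth from an infected mother is symbiont-free
  with probability φ; a vertically transmitting coinfected mother produces
  A-only, B-only, or coinfected offspring with probabilities c_A, c_B,
  1 − (c_A + c_B). For example
  S_i′ gains ν_b[φ(X_i + I_Ai + I_Bi) + S_i], and
  X_i′ gains ν_b(1 − φ)(1 − (c_A + c_B))X_i, so total births are ν_b N.
* **Frequency-dependent horizontal transmission** — the force of infection
  of symbiont A is β_A (I_A + qX)/N_it: coinfected hosts transmit with
  modifier q, and singly infected hosts acquire the second symbiont with
  susceptibility modifier ψ, e.g.
  I_A′ gains β_A(I_A + qX)S/N_it − ψβ_B(I_B + qX)I_A/N_it.
* **Migration** — hosts emigrate at per-capita rate m and are routed to
  other patches by a column-stochastic matrix ρ[i, l] (destination, source),
  optionally built from pairwise distances with an exponential kernel.

Two reductions are first-class citizens: the closed-population
**two-symbiont experiment model** (horizontal transmission only; four
parameters β_A, β_B, q, ψ) and the **single-symbiont SI model**
I′ = βI(N − I)/N, whose logistic solution doubles as an exact oracle for
the integrator.

Observed data are modelled as binomial (one symbiont) or multinomial (two
symbionts) draws of the assayed hosts' infection classes, giving the
likelihood P(D | θ) used for MCMC sampling of the posterior, with vague
half-Normal(0, 5) priors by default and WAIC for comparing model variants.

## Worked example

Simulate a release experiment — one infected host dropped into 49
susceptibles, three replicate populations, full census every 2 days with
binomial observation error, true β = 0.5 day⁻¹ host⁻¹ — and re-estimate β:

```r
library(symbiodyn)
series <- simulate_release_experiment(beta = 0.5, seed = 1)
fit <- fit_transmission(series)   # 3 chains x 5000 iter, 2000 warm-up, thin 3
summary(fit)
```

```
Posterior summary (pooled chains) with convergence diagnostics
 parameter   mean   q2.5   q50  q97.5  rhat  ess
      beta 0.5079 0.4879 0.508 0.5275 1.001 1521
```

The posterior median (0.508) sits on the generating rate and the 95%
credible interval [0.488, 0.528] covers it; split R-hat ≈ 1 says the three
chains agree. `predict(fit)` returns the posterior median trajectory and
credible band of the infected fraction, `plot(fit)` draws them over the
data, and `compare_models()` ranks model variants fitted to the same series
by expected log predictive density:

```r
sc  <- simulate_coinfection_experiment(seed = 5)   # 4 populations of 100
full <- fit_transmission(sc, control = mcmc_control(n_iter = 2500,
                                                    n_warmup = 1000, seed = 5))
summary(full)
```

```
 parameter   mean   q2.5    q50  q97.5  rhat   ess
    beta_A 0.5101 0.4877 0.5097 0.5351 1.000 229.5
    beta_B 0.3557 0.3347 0.3556 0.3766 1.005 244.4
         q 0.7092 0.6381 0.7094 0.7866 1.008 203.5
       psi 1.3210 1.1842 1.3190 1.4734 1.017 234.8
```

All four intervals cover the generating values (0.5, 0.35, 0.75, 1.25).

A command-line wrapper (`inst/cli/symbiodyn`) exposes the same pipeline:
`release`, `coinfection`, `simulate`, `fit`, `compare`; see
`?run_cli`.

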