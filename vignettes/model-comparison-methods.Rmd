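---
title: "Comparing dynamical models of network motifs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing dynamical models of network motifs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifcompare)
```

## The problem

Small regulatory circuits — network motifs — recur throughout transcription
networks: a single input driving two targets (SIM), a regulatory chain (RC),
the feed-forward loop (FF) and negative feedback (FB). Converted to
differential equations, several motif architectures are often compatible with
the same time-series data, and the feed-forward loop itself admits several
parameterizations (coherent or incoherent branch signs, AND or OR promoter
logic, with or without transcriptional delays). `motifcompare` implements the
full statistical machinery for deciding between such candidate models from
noisy time courses: simulation of the study designs, Bayesian parameter
inference by MCMC, and model ranking by marginal likelihood, DIC, Bayes
factors, maximum likelihood, AIC and likelihood-ratio tests.

## Models

All sixteen registered models (see `motif_models()`) share the same
structure: each species has a production term and a first-order degradation
term. The linear motifs use mass-action-like production (`beta * S`,
`beta * y`); the cooperative `.H` variants and the feed-forward subtypes use
Hill rate laws, with activation $f^+(s) = s^h/(\theta^h + s^h)$ and
repression $f^-(s) = \theta^h/(\theta^h + s^h)$. Two inputs meeting at one
promoter are combined by a gate: AND is the product $f_S f_y$; for OR the
algebra is not uniquely fixed by the biology, and we use the probabilistic
sum $f_S + f_y - f_S f_y$, which stays in $[0,1]$, is monotone in each input,
and reduces to boolean OR at saturation (capped sum and max are the obvious
alternatives; the choice only matters in the mid-activation regime).

The Hill coefficient is fixed at $h = 2$ everywhere and never estimated. For
data generation all thresholds sit at $\theta = 0.5$ and all rate constants
at 1. In the feed-forward subtype study the three thresholds are estimated
alongside the four rate constants (seven parameters; the delay models add an
eighth, $\tau$), because the subtypes are distinguishable precisely through
where their gates sit relative to the trajectories. The `.H` variants keep
their thresholds fixed, matching their role as drop-in cooperative analogues
of the linear motifs with identical penalized parameter counts.

Two delay models extend the OR-gated coherent loop. In the first, the gate
reads the intermediate regulator a lag $\tau$ ago; in the second, the delay
additionally affects the intermediate's own input, i.e. the first equation
reads the signal at $t - \tau$ while the target's direct signal input remains
undelayed. Before the start of a step experiment the state history is held
constant at the initial state, and the signal history is the complementary
step's level (an ON step was preceded by the OFF level and vice versa), so
lagged signal lookups are meaningful. The feedback motif's first equation is
closed with end-product repression, $\beta_y S f^-(z, \theta_{zy}, 2)$, with
the threshold estimated — giving the five penalized parameters its AIC
bookkeeping requires.

AIC and likelihood-ratio penalties count estimated rate, threshold and delay
parameters only; the observation noise variance is excluded throughout.

## Study designs and the synthetic-data generator

The four-motif study drives each motif with the staircase signal
$S = \{0, 1, 2, 0\}$ switching at $t = \{0, 2, 6, 10\}$, observes both state
variables at 30 equally spaced times across $[0, 10]$ (60 records), and adds
independent Gaussian noise with standard deviation 0.05. The feed-forward
designs mirror the bacterial step experiments: an ON step (signal 1, states
starting at 0) and an OFF step (signal 0, states starting at 1), with only
the target $z$ observed and the intermediate hidden — 30 + 30 points for the
arabinose-like design (truth: coherent AND loop), 20 + 17 for the
flagella-like design (truth: coherent OR loop), and 15 ON-only points for the
galactose-like design (truth: incoherent AND loop). The step duration is not
dictated by the designs' dimensionless units; we use 10 time units per step
(several relaxation times at unit rates), configurable. The same noise level,
0.05, is reused for these designs.

What the generator deliberately does *not* emulate: real transcription data
have correlated, often multiplicative errors, irregular sampling, and
normalization artefacts; the generator's errors are i.i.d. Gaussian on the
stated grid. Passing tests therefore demonstrate the statistical machinery
under the stated assumptions, not robustness to real-data pathologies.

## Inference

The likelihood is Gaussian: independent homoscedastic errors around the
deterministic solution. Priors are log-normal (mean 0, sd 1 in log space) for
every kinetic parameter. The noise prior is inverse-gamma with shape 0.5 and
scale 0.05, placed on the noise *standard deviation* $\sigma$: its mode
$b/(a+1) = 0.1/3$ then brackets the generating noise level, and — decisive
for us — the evidence and DIC values of the simulation studies only come out
on their reported scale under this reading (placing the same prior on
$\sigma^2$ punishes the posterior by $e^{-b/\sigma^2}\approx e^{-20}$ at the
generating noise level and drags the log evidence down by roughly fifteen
units). Archives and summaries still report the variance `sigma2`.

Sampling is random-walk Metropolis in log-parameter space, where the
log-normal priors are standard Gaussians and positivity is automatic; the
inverse-gamma prior carries its change-of-variables Jacobian. The proposal is
a symmetric multivariate Gaussian whose covariance is re-estimated during
burn-in from the recent sample path (scaled by the usual $2.38^2/d$), with a
global factor tuned towards 20–40% acceptance; both are frozen when burn-in
ends, so the retained draws come from a fixed Markov kernel and the
stationary distribution is untouched. Chains start from independent prior
draws, re-drawn if the initial solve fails; integration failures during
sampling are treated as log-likelihood $-\infty$ (auto-rejection) and
counted. The full protocol is five chains of 40,000 iterations, burn-in
20,000, thinning 10; the reduced preset (3 × 8,000, burn-in 4,000, thinning
5) is used for replicated ranking and coverage studies. Convergence is
checked with the classic Gelman–Rubin statistic on the retained draws
(threshold 1.05), computed on the log scale to match the sampling space.

Numerical integration uses an adaptive Cash–Karp Runge–Kutta 4/5 scheme
restarted at the signal's breakpoints (so step discontinuities never cross an
integration step), with tolerances `rtol = 1e-8`/`atol = 1e-10` for
trajectory work and `1e-6`/`1e-8` inside the MCMC likelihood for speed. The
delay models use the method of steps with a fixed-step classical Runge–Kutta
scheme whose step never exceeds the lag (capped at 0.02, floored at $10^{-3}$
with clamped history lookups for vanishing lags — a vanishing lag makes the
delay irrelevant anyway). The integrator is validated in the test suite
against matrix-exponential closed forms for the linear motifs (relative error
$\le 10^{-6}$ on the study grid) and against an independent general-purpose
ODE/DDE solver for the nonlinear and delayed models.

## Model comparison

The marginal likelihood $p(Y \mid M)$ is estimated by reciprocal importance
sampling from the posterior draws, with a multivariate $t$ auxiliary density
fitted to the draws in log space (location = mean, scale = covariance,
4 degrees of freedom — heavy tails keep the weights bounded; the choice is
exposed as `t_dof`). All averages use log-sum-exp; the prior densities carry
the Jacobian so the estimate is parameterization-consistent, and a
Monte-Carlo standard error from 20 consecutive batches is attached to every
estimate. A singular draw covariance (possible when a parameter is pinned) is
ridge-regularized with a warning. Bayes factors between evidences use the
conventional qualitative cutoffs (1: weak, 3: substantial, 10: decisive,
100: overwhelming).

For DIC we report, by default, the *concentrated* deviance: the noise
variance is replaced draw-by-draw by its conditional maximum
$\mathrm{RSS}(\theta)/N$, so the deviance depends on the kinetic parameters
only and $p_D$ counts effective kinetic parameters — the same convention as
the AIC penalty, and the one under which a well-identified four-rate motif
shows $p_D \approx 4$. The textbook joint deviance (sampled $\sigma^2$
included, adding about one unit for a well-identified noise parameter) is
available via `deviance = "joint"`, and the posterior mean may be taken on
the natural scale (default) or as a back-transformed log-scale mean
(`mean_scale = "log"`); the natural-scale mean is what makes the deviance at
the posterior mean sit essentially at the maximum-likelihood point for these
well-identified fits. DIC for badly misspecified models can be unstable; a
failed solve at the posterior mean flags the result rather than dropping it.

Maximum likelihood is taken as the best stored draw across all chains — the
contract is explicitly the stored-draw maximum, not a polished optimum. The
frequentist route (`least_squares_fit()`) minimises the residual sum of
squares in log-parameter space from multiple starts, estimates
$\hat\sigma^2 = \mathrm{RSS}/(N - p)$ without bias, and derives 95%
confidence intervals from the curvature of the objective
($\mathrm{cov} = \hat\sigma^2 (H/2)^{-1}$); a singular Hessian — e.g. a rate
that the design leaves unidentified — keeps the point estimate and flags the
intervals as unavailable.

## Experiment drivers and reproducibility

`run_motif_grid()` regenerates the four-motif identifiability grid (simulate
from each motif, fit all four, rank); `run_ff_grid()` does the same for the
three feed-forward designs against each system's own control circuit, and a
`flagella_extension` study adds the delay models. Every per-dataset and
per-fit seed is derived from one master seed by fixed offsets, so a rerun is
reproducible draw for draw. Ties within one log unit of evidence are flagged
with the pragmatic fewer-parameters preference noted, never enforced.

Problem sizes used by the shipped tests: the full protocol for the headline
SIM/RC/FF fits; the reduced preset for the five-seed ranking-recovery study
and for the coverage study (20 replicates per motif, pooling the
per-parameter 95% credible intervals). At these sizes the whole suite runs in
minutes on one core.

## Known limitations

- The OR-gate algebra and the exact delay placement in the second delay
  model are reconstructions from the gate templates; both are isolated in
  single functions (`gate()`, the model registry) and easy to swap.
- Evidence values inherit the seed-to-seed spread of the simulated data
  (about ±5 log units at this design, dominated by the realized noise
  variance); comparisons *between* models on the same dataset are far more
  stable than absolute values.
- The reciprocal importance sampler is adequate for these unimodal, low-
  dimensional posteriors; strongly multimodal posteriors would need bridge
  or path sampling.
- Delay-model posteriors mix slowly at the reduced preset when the data
  carry no delay signal (the lag is then unidentified); use the full
  protocol for serious delay-model comparisons.

## A worked example

```{r example, eval = FALSE}
library(motifcompare)

data <- simulate_motif_dataset("FF", seed = 1)
fits <- lapply(
  setNames(, c("SIM", "RC", "FF", "FB")),
  function(m) run_metropolis(data, m, config = chain_config(preset = "reduced"),
                             seed = 1)
)
rank_models(fits, data)
```
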