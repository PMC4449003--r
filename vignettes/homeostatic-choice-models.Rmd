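---
title: "Homeostatic choice models for foraging gambles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic choice models for foraging gambles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragefit)
```

## The scientific problem

Organisms that must keep an internal variable (energy, here) above a lethal
boundary face decisions whose risk is not captured by the endpoint outcome
alone: a trajectory that touches zero is fatal even if the expected endpoint
is high. `foragefit` implements an analysis pipeline for binary-choice
experiments built on that idea. Participants choose between two "foraging
environments", each a short sequence of risky days: every day costs one
energy point for sure, and with probability $p$ returns a gross gain $g$.
Starting from energy $x_0$ with a horizon of $n$ days, the trajectory is a
random walk on the non-negative integers with steps $+(g-1)$ (probability
$p$) and $-1$ (probability $q = 1-p$), and an absorbing boundary at zero
("starvation"). The same endpoint distributions, presented as single-spin
lottery wheels, give a matched "casino" frame with no foraging narrative.

The pipeline asks which of twelve candidate decision models best explains
choices, the central contrast being whether the probability of hitting the
boundary, $p_{\text{starve}}$, carries explanatory weight beyond standard
economic quantities (moments of the endpoint distribution, or rank-dependent
utility).

## The gamble engine

`enumerate_walk()` computes the exact endpoint distribution of the absorbed
walk by propagating the state distribution one day at a time: mass at zero
stays at zero, mass at $s > 0$ splits into $p$ at $s + g - 1$ and $q$ at
$s - 1$. This is algebraically identical to summing probability products
over all $2^n$ success/failure paths of the decision tree (the test suite
keeps that brute-force enumerator as an independent oracle), but aggregates
by state at each step. With $n \le 3$ in the study design the arithmetic is
a handful of exact float operations; no closed-form binomial shortcut is
needed, and the implementation places no practical limit below $n \approx 10$.

For the worked example $x_0 = 2$, $n = 3$, $g = 3$ the engine reproduces the
closed forms $p_{\text{starve}} = q^2$ and $P(\text{endpoint} = 2) = 2pq^2$
exactly for every $p$.

`compute_stats()` returns expected value, variance and skewness of the
endpoint distribution plus $p_{\text{starve}}$. Skewness is the
*standardized* third central moment, $\sum_j p_j (x_j - \mu)^3 / \sigma^3$ —
the published range of the skewness variable ($-2.67$ to $2.00$, mean $0$)
is only consistent with a unitless measure, and standardization is the
convention of the risk-return literature. A degenerate distribution
($\sigma = 0$) gets skewness 0 by convention; it cannot arise from a valid
walk but can from hand-built distributions.

### The gamble-set generator

`generate_gamble_set()` reproduces the structure of the study's 480 gamble
pairs: 120 pairs for each combination $(x_0, n) \in \{(1,1), (1,2), (2,2),
(2,3)\}$; both options of a pair share $(x_0, n)$ because a trial has a
single energy bar and day count. Gains are uniform on $\{2, \dots, 6\}$ and
success probabilities uniform on $[0.008, 0.9]$ rounded to three decimals —
the published ranges. Pairs are redrawn until both options have
$p_{\text{starve}}$ strictly inside $(0, 1)$ and the options differ. The
published summary table also reports tighter realized ranges of EV and
$p_{\text{starve}}$ than uniform sampling of $p$ yields, which implies
additional unpublished screening of the original list; we deliberately do
not guess at it, so summary moments of generated sets are close to, but not
identical with, the published ones. All structural invariants (counts,
ranges, positive starvation risk) hold exactly.

## The decision models

All models feed a value difference through the softmax rule
$P(\text{choose 1}) = 1 / (1 + e^{-(V_1 - V_2)/\beta})$ with decision noise
$\beta > 0$.

| id | value rule | free parameters |
|----|-----------------------------|------------------|
| 1  | $V = EV$ | $\beta$ |
| 2  | $V = EV + \rho\,Var$ | $\beta, \rho$ |
| 3  | $V = EV + \lambda\,Skw$ | $\beta, \lambda$ |
| 4  | $V = EV + \rho\,Var + \lambda\,Skw$ | $\beta, \rho, \lambda$ |
| 5  | RDU, Prelec-I weighting | $\beta, \mu, \alpha$ |
| 6  | RDU, Prelec-II weighting | $\beta, \mu, \alpha, \beta_w$ |
| 7  | $V = EV + \xi\,p_{starve}$ | $\beta, \xi$ |
| 8  | $V = EV + \rho\,Var + \xi\,p_{starve}$ | $\beta, \rho, \xi$ |
| 9  | $V = EV + \rho\,Var + \lambda\,Skw + \xi\,p_{starve}$ | $\beta, \rho, \lambda, \xi$ |
| 10 | $V = EV + [f\,\xi_{forag} + (1-f)\,\xi_{casino}]\,p_{starve}$ | $\beta, \xi_{forag}, \xi_{casino}$ |
| 11 | $V = p_{starve}$ | $\beta$ |
| 12 | $V = EV + \sum_k d_k\,\xi_{d_k}\,p_{starve}$ | $\beta, \xi_{d_1}, \xi_{d_2}, \xi_{d_3}$ |

Models 1–4 form the moments family, 5–6 the rank-dependent utility family,
7–9 (and the frame-split 10) the homeostatic family; 11–12 are supplementary
variants. The rank-dependent models value an option as
$V = \sum_j \pi_j\,u(x_j)$ with power utility $u(x) = x^\mu$, $u(0) = 0$,
and decision weights from the Prelec weighting function
$w(p) = \exp(-\beta_w(-\log p)^\alpha)$ ($\beta_w = 1$ for the
one-parameter variant).

**Ranking convention.** The cumulative structure of rank-dependent weights
requires an ordering of outcomes, and published presentations of the weight
recursion are frequently ambiguous about its direction. We rank outcomes
*best first*: $\pi_1 = w(p_{\text{best}})$, and each subsequent weight is the
successive difference of $w$ applied to the cumulative probability of
outcomes at least as good. This is the standard convention for gains in the
rank-dependent literature; the identity-weighting reduction
($\mu = \alpha = \beta_w = 1 \Rightarrow V = EV$) holds under any ordering
and is tested, so the convention matters only for curved weighting. The
ranking is internal: storage order of a distribution is irrelevant.

**Parameter constraints.** $\beta$, $\mu$, $\alpha$, $\beta_w$ must be
positive and are optimized on the log scale; the linear weights ($\rho$,
$\lambda$, $\xi$ and variants) are unconstrained — the scientific question
is precisely the sign of $\xi$. The Prelec elevation parameter is named
`beta_w` to keep it distinct from the softmax noise.

## Maximum-likelihood fitting

`fit_participant()` minimizes the summed negative log-likelihood of a
participant's non-missed trials with a Nelder–Mead simplex search
(function tolerance $10^{-6}$, at most $2000k$ evaluations for $k$
parameters). Three numerical choices worth knowing:

* **Seeding.** The first run starts every raw parameter at $+0.5$; if it
  fails to converge, a second run starts the unconstrained parameters at
  $-0.5$, and the better converged result is kept. Non-convergence is
  operationalized as the optimizer hitting its evaluation cap or returning a
  non-finite value.
* **Restart polishing.** After convergence the simplex is restarted from the
  incumbent until the improvement falls below 0.01 nats (at most 3
  restarts). Ridge-shaped likelihoods — skewness and $p_{\text{starve}}$
  differences are strongly correlated across gambles, so the four-parameter
  model 9 has one — otherwise occasionally stop short, which would violate
  the nesting guarantee that a superset model never fits worse.
* **One-parameter models** (1 and 11) use Brent line search on the log-noise
  scale instead, bounded at $e^{\pm 25}$; a 1-D simplex is not reliable.
* **Clipping.** Choice probabilities are clipped to
  $[10^{-10}, 1 - 10^{-10}]$ before logs so near-deterministic fits keep a
  finite likelihood; the clip bound is part of `fit_options()` and hence of
  the provenance record.

Model evidence is approximated per participant by information criteria on
the *half* scale: $BIC = -\ln L + \tfrac12 k \ln n$ and $AIC = -\ln L + k$,
with $n$ the participant's non-missed trial count. On this scale $-BIC$ is
directly a Laplace-style log-evidence approximation, which is what the
group-level machinery consumes; users of the conventional $-2\ln L$ scale
should double before comparing elsewhere.

## Group-level model comparison

Fixed effects: `log_group_bayes_factors()` subtracts a reference model's
criterion per participant and sums over the group; smaller is better.

Random effects: `bms_random_effects()` treats each participant's model
identity as drawn from population frequencies with a Dirichlet prior and
fits the standard variational approximation (participant-wise posterior
assignments proportional to $\exp(\text{log evidence} + \psi(\alpha_m) -
\psi(\sum \alpha))$, Dirichlet counts updated to prior plus summed
assignments, iterated to $10^{-6}$). Exceedance probabilities — the
posterior probability that a model is the most frequent — are estimated by
Monte-Carlo arg-max counting over Dirichlet draws (default $10^6$, seeded;
for two models the Beta tail is exact and is used as a cross-check in the
tests). `family_bms()` equalizes prior mass across families (total mass 1
per family, split equally among members) and sums sampled frequencies
within families before the arg-max. One caveat the tests respect: with
*exactly* equal evidences and unequal family sizes, the variational
fixed point is not symmetric under the size-corrected prior — the
equal-evidence symmetry check is therefore posed with equal-size families,
and informative-evidence behaviour (dominance, count conservation,
permutation equivariance) is tested separately.

Parameter-level inference across participants uses the exact sign test
(`sign_test()`, a two-sided exact binomial test on the count of positive
values, ties at the null dropped).

## The synthetic cohort

`simulate_cohort()` is the package's test bed and demo data source. Defaults
mirror the study conditions: 22 agents, a fresh 480-pair gamble set, both
frames with casino blocks first, 960 trials per agent, and a
missed-trial rate of 2/960 (missing completely at random — only the average
count is published). The default generating model is the frame-split
homeostatic model with population medians $\beta = 0.5$,
$\xi_{\text{foraging}} = -3$, $\xi_{\text{casino}} = -1.5$, chosen once to
mirror the qualitative published pattern (weights negative, foraging weight
below casino weight); between-agent spread (log-normal for positive
parameters, normal otherwise, SDs 0.25/0.75/0.5) is our choice of a
realistic individual-differences scale. These are synthetic demo settings,
not estimates. Note a genuine identifiability feature they expose: with the
frame weights only 1.5 apart, the two-parameter nested model often survives
the extra-parameter penalty at 960 trials, so closure tests assert family
identity, not the frame-split winner.

Reaction times are generated from the same structure the RT analysis
assumes: $\log RT$ linear in the absolute between-option differences in EV
and $p_{\text{starve}}$ and their interaction, with participant random
intercepts and slopes and Gaussian noise, on the log-millisecond scale
(intercept 7 ≈ 1.1 s; negative difficulty slopes; positive interaction).

What the generator does *not* emulate: learning or fatigue across blocks,
any systematic structure in missed trials, non-log-normal RT tails, and any
screening of gamble pairs beyond the structural constraints. Passing
recovery tests therefore show the pipeline is consistent and well calibrated
under its own assumptions — not that real participants satisfy them.

## Reaction-time analysis

`fit_rt_model()` fits
$\log RT \sim \Delta EV \ast \Delta p_{starve} + (1 + \Delta EV \ast
\Delta p_{starve} \mid \text{participant})$
by maximum likelihood via `lme4::lmer` (ML, not REML, because fixed-effect
structures are compared by likelihood-ratio tests; REML likelihoods are not
comparable across fixed-effect structures). Predictors are the uncentered
absolute differences. Each fixed effect's p-value comes from an LRT against
the model with that single term dropped. If the full random-effects
covariance is singular or fails, the structure is reduced stepwise with a
warning. No RT trimming is applied by default.

## Problem sizes used in validation

The test suite validates at sizes chosen to keep a full run comfortably
interactive while leaving no statistical check underpowered: recovery uses
20 agents per model at the full 960 trials; replicate-level closure uses 20
cohorts of 12 agents × 480 trials; RT calibration uses 24 null and 40
effect replicates of 8 participants × 120 trials. The acceptance script
analyses one full study-shaped cohort (22 × 960, ten models) end to end.

## Known limitations

* Walks are discrete-time with a hard boundary; soft boundaries or
  continuous time are out of scope.
* No hierarchical (empirical-Bayes) fitting across participants; every
  participant is fitted independently, as in the original procedure.
* The rank-dependent models apply to gains only ($u(0) = 0$, non-negative
  outcomes); mixed gambles with losses are not supported.
* The exact composition of the original 480-pair list is not published;
  analyses of real data should load it rather than regenerate it
  (`load_dataset()` reads the documented CSV schema; MATLAB containers must
  be exported to CSV first).
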