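---
title: "Testing preferential attachment in contact-count data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing preferential attachment in contact-count data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patest)
```

## The question

Contact surveys consistently find heavy right tails in the number of
distinct people a respondent meets per day. One mechanistic explanation is
preferential attachment (PA): people who already have many contacts gain
new ones faster. PA matters epidemiologically because the early growth
rate of an epidemic on a contact network scales with the *second moment*
of the degree distribution; if PA is strong enough to make that moment
diverge, no amount of untargeted vaccination could control transmission.
`patest` tests PA directly, by likelihood, instead of inferring it from
approximate power-law tails.

## The model

Each individual starts the day with zero contacts and accumulates them as
a pure-birth continuous-time Markov chain: with $k$ contacts already held,
a new one arrives at rate

$$f_k = 1 + \tau k, \qquad \tau \ge 0 .$$

PA is the statement $\tau > 0$; $\tau$ is a dimensionless gain per
existing contact. Time is measured in units of the base contact-making
rate, so the base rate is exactly 1 and is not a parameter. A per-phase
contact rate would be statistically indistinguishable from spending a
different amount of time in the phase, which is why phases differ only in
their exit behaviour.

The time available for making contacts is random. We give it a
phase-type law: the individual starts in activity phase
$a \in \{1,\dots,m\}$ with probability $\nu_a$, moves from phase $a$ to a
*later* phase $b > a$ at rate $Q_{a,b}$, and stops altogether at rate
$\mu_a$. Phases stand in for the sequence of daily activities (commuting,
work, leisure, ...). Phase-type distributions are dense in the positive
continuous laws, so with enough phases the holding time can approximate
any duration distribution while staying mechanistically interpretable and
computationally cheap. The total exit rate of phase $a$ is
$M_a = \mu_a + \sum_{b>a} Q_{a,b}$, and every phase must have $M_a > 0$
so the process ends almost surely.

With $m$ phases the free parameters are $m-1$ initial probabilities (the
simplex absorbs one), $m$ stopping rates, $m(m-1)/2$ transition rates,
plus $\tau$ when PA is included:

```{r params}
sapply(1:6, function(m) {
  sp <- phase_type(rep(1/m, m), rep(1, m),
                   upper_tri_matrix(rep(1, (m*(m-1)) %/% 2), m))
  c(no_pa = count_parameters(pa_model(sp, pa = FALSE)),
    pa = count_parameters(pa_model(sp, tau = 0.1, pa = TRUE)))
})
```

## Conditional law at fixed time

Conditional on $t$ units of activity, the contact count has probability
generating function

$$g(t,s) = \bigl(s - (s-1)e^{\tau t}\bigr)^{-1/\tau}
         = e^{-t}\bigl(1 - (1 - e^{-\tau t})\,s\bigr)^{-1/\tau},$$

a negative binomial with size $1/\tau$ and success probability
$e^{-\tau t}$, degenerating to Poisson with mean $t$ as
$\tau \downarrow 0$. `pmf_conditional()` evaluates it in log space, using
the rising-factorial sum $\sum_{j<k}\log(1/\tau + j)$ rather than a
difference of two large `lgamma` values, so small $\tau$ and large $k$
lose no precision; below $\tau = 10^{-8}$ all $1/\tau$ expressions switch
to their analytic Poisson/linear limits to avoid catastrophic
cancellation. Raw moments come from the closed-form factorial moments
$m_1^j\prod_{i<j}(1+i\tau)$ (with $m_1 = (e^{\tau t}-1)/\tau$) via
Stirling numbers, which gives $m_1$ and
$m_2 = m_1 + (\tau+1)m_1^2$ for orders one and two and exact values for
any higher order. The test suite checks the pmf against an independent
oracle — the Taylor coefficients of $g$ extracted by FFT on the complex
unit circle — and the moments against truncated sums.

## The unconditional degree distribution

The quantity the likelihood needs is
$d_k = \int_0^\infty \rho(t)\,p_k(t)\,\mathrm{d}t$, with $\rho$ the
phase-type density. Quadrature of that integral for every $k$ would be
slow and fragile in the tail. Instead, write
$p_{a,k}(t)$ for the probability of being in phase $a$ with $k$ contacts;
Laplace-transforming its master equation at frequency zero turns the
time-integrated occupancies $A_{a,k}$ into a *triangular* linear system,

$$(f_k + M_a)\,A_{a,k} = \nu_a\,\delta_{k,0} + f_{k-1}A_{a,k-1}
   + \sum_{b<a} Q_{b,a} A_{b,k}, \qquad d_k = \sum_a \mu_a A_{a,k},$$

solved forward in $(k, a)$ at cost $O(m^2 k_{\max})$ with no matrix
inversion. Two sign/orientation choices deserve note, because the
symbolic forms in circulation are easy to transpose:

* the initial condition enters *positively* (the transform of
  $\mathrm{d}p/\mathrm{d}t$ contributes $-p_{a,k}(0)$, which moves
  $\nu_a$ to the right-hand side); any other sign makes $A$ negative;
* $M_a$ must be the total *out*-rate of phase $a$ (stopping plus onward
  transitions), which is also what makes $\rho$ integrate to one.

Both choices are pinned down by invariants the suite enforces:
$A_{a,k} \ge 0$, $\sum_k d_k \to 1$, and machine-precision agreement with
direct quadrature on multi-phase fixtures.

Truncation: by default $k_{\max}$ doubles until the residual tail mass
drops below $10^{-10}$ (hard cap $10^5$, with a warning that reports the
remaining mass); the fitting path instead uses the largest observed
degree and never silently renormalises. `censor_zero()` applies the
zero-truncation $\tilde d_0 = 0$, $\tilde d_{k>0} = d_k/(1-d_0)$ used for
survey data in which zero-contact respondents cannot appear; it is
idempotent and refuses the degenerate $d_0 = 1$.

## Moments and divergence

The $r$-th unconditional moment involves
$\mathcal I_r = \int e^{r\tau t}\rho(t)\,\mathrm{d}t$. Because the phase
generator $G$ is triangular with eigenvalues $-M_a$, the integral is the
explicit linear solve
$\mu^\top(-(G^\top + r\tau I))^{-1}\nu$, finite exactly when
$r\tau < M_a$ for every phase $a$; the package combines
$\mathcal I_1, \mathcal I_2$ into the first two moments
($\bar m_1 = (\mathcal I_1 - 1)/\tau$, with the $\tau = 0$ limits
$E[T]$ and $E[T] + E[T^2]$ handled separately). Two conventions we adopt
and document rather than leave implicit:

* **Boundary**: at $r\tau = M_a$ exactly the integrand tends to a
  constant, so the moment is classified *divergent* (the strict
  inequality is widened to $\ge$ at the boundary).
* **Reachability**: a phase with $\nu_a = 0$ and no inbound transitions
  can never be occupied, so it cannot drive divergence;
  `lowest_divergent_moment()` scans only phases reachable with positive
  probability.

`pa_contribution()` quantifies how much of the mean degree the attachment
mechanism accounts for: it sets $\tau = 0$ with the phase parameters
fixed and reports the ratio of counterfactual to fitted mean.

## Likelihood, fitting and uncertainty

For counts $y_k$ of respondents reporting $k$ contacts, the model is a
zero-truncated multinomial; the log-likelihood is
$\sum_k y_k \log \tilde d_k$ with the data-only combinatorial constant
dropped (it cancels from every comparison). Degrees the trial model makes
impossible return a $-10^{12}$ sentinel instead of an error so the
optimiser can move away.

The surface is smooth in $\tau$ but multimodal in the phase parameters,
so `fit_mle()` optimises an unconstrained reparameterisation — log rates,
and a softmax for $\nu$ with the first logit pinned at zero for
identifiability — by simulated annealing from multiple random starts
(rates log-uniform on $[10^{-3}, 10]$, $\nu$ uniform on the simplex),
each followed by a derivative-free Nelder–Mead polish (Brent line search
in the one-parameter case). The defaults, 20 starts and $2\times10^4$
annealing evaluations per start, are this package's own choices: the
method class (multi-start annealing) is standard for this problem, but no
canonical schedule exists, so the defaults were set to be comfortably
conservative for $m \le 6$ and are fully adjustable through
`fit_settings()`. Test-suite fits use reduced budgets (3–5 starts,
300–1500 evaluations) at which we verified — against larger budgets and,
for one-phase models, a closed-form/1-d-search oracle — that the same
optima are reached at the problem sizes tested. All randomness descends
from one seed through a fixed splitting scheme, so every fit, bootstrap
replicate and simulated dataset is individually replayable.

Uncertainty is bootstrap-only (no Hessian standard errors):
`bootstrap_ci()` resamples respondents nonparametrically and refits
(warm-started at the original optimum); `parametric_bootstrap_band()`
simulates datasets from the fitted model, refits each, and envelopes the
refitted pmfs — the uncertainty band for the predicted degree
distribution. Percentile intervals are reported; with several phases,
label switching means multi-phase rate intervals should be read
per-parameterisation, while $\tau$ is unaffected.

## Model selection and the boundary problem

`selection_grid()` fits all $(m, \mathrm{PA})$ cells up to `m_max`,
warm-starting each cell from the optima of the models nested in it (an
extra phase enters with negligible initial probability and small rates; PA
enters with $\tau \approx 0$), which keeps log-likelihoods monotone along
nesting chains up to optimiser tolerance. The table reports parameter
counts, $\Delta$AIC and $\Delta$BIC against the grid minima, and the
lowest divergent moment of each PA model.

`lrt()` accepts only informative nestings: PA added at fixed $m$, or
phases added at fixed PA status (an extra phase collapses to the null by
zeroing its inbound rates). Testing PA puts the null $\tau = 0$ on the
boundary of the parameter space, where the usual $\chi^2_1$ reference is
conservative — the asymptotic null is really a 50:50 mixture of a point
mass at zero and $\chi^2_1$. The default keeps the plain $\chi^2$
reference for comparability with common practice and flags the
conservativeness; `boundary = TRUE` applies the mixture correction. The
acceptance suite measures the realised size: at $n = 5000$ under
$\tau = 0$, the plain test rejects at the 5% level in roughly 2–3% of 200
replicates, as boundary theory predicts.

## The simulator: generator and oracle

`simulate_degrees()` is an exact event-driven (Gillespie) simulation:
competing exponential clocks for contact, phase move and stop, sampled by
total rate plus categorical choice — no thinning, no discretisation —
because the simulator doubles as the independent oracle for the solver
(total-variation, chi-square and Kolmogorov–Smirnov agreement are all
tested). Zero-degree individuals are discarded *post hoc* when censoring
is requested, mirroring surveys that simply contain no zero-contact
respondents; the retained count becomes $n$. Whether zero reports were
structurally impossible or merely absent in real instruments is
unknowable from such data; discarding is our convention and only the
retained sample enters the likelihood either way.

What the generator emulates: independent respondents, one day's contact
accumulation, integer counts, zero-censoring. What it does not: reporting
error and heaping (real surveys show spikes at round numbers), household
or network structure linking respondents, day-of-week effects, and
repeated-contact weighting. Passing tests therefore demonstrate that the
pipeline recovers the truth *when the model class is the data-generating
process*; on real data the phase structure absorbs, but does not explain,
those extra features.

## Study conditions used by the test suite

The fixture models place rates on the scale of the base contact rate so
mean degrees land where daily-contact surveys do (≈ 7–20): a
one-phase/no-PA model ($\mu = 0.05$), a one-phase PA model
($\mu = 0.05$, $\tau = 0.02$, third moment divergent), a two-phase PA
model ($\nu = (0.6, 0.4)$, $\mu = (0.3, 0.12)$, $Q_{1,2} = 0.2$,
$\tau = 0.05$; second moment finite, third divergent) used for the
recovery studies, a three-phase mild-PA model, and a deliberately
heavy-tailed one-phase model ($\mu = 0.08$, $\tau = 0.05$) whose second
moment diverges. Recovery and coverage use $n = 5000$ respondents with 20
replicate datasets and 60-replicate bootstraps; test size uses 200
replicate datasets; selection sanity uses $n = 10^4$ with 10 replicates;
solver–simulator agreement uses $10^5$ draws.

## Known limitations

* Phases are visited in increasing order only (strictly triangular $Q$);
  this is what makes the solver triangular and the parameter count match
  the $m(m-1)/2$ rule, but it excludes cyclic activity patterns.
* `moment_degree()` implements orders one and two (the epidemiologically
  relevant ones); higher orders are available conditionally on $t$ via
  `moment_conditional()` and by truncated sums over `degree_pmf()`.
* Near-boundary models ($r\tau \lesssim M_a$) have genuinely slow pmf
  tails; the truncation cap then leaves reported tail mass, which is
  surfaced as a warning rather than renormalised away.
* The bootstrap refits inherit the optimiser's budget; with very small
  budgets the intervals narrow toward the warm start. The defaults are
  sized so this effect is negligible at survey-scale $n$.
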