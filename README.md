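# patest — testing preferential attachment in contact-count data

`patest` asks a concrete epidemiological question of ordinary survey
data: do people who already have many social contacts gain new ones
faster? That mechanism — preferential attachment (PA) — is usually hunted
indirectly through approximate power-law tails. `patest` instead tests it
directly by maximum likelihood, using a mechanistic model cheap enough to
fit and compare many variants.

It is aimed at infectious-disease modellers and network scientists with
integer count data (contacts per respondent per day, or any count where
"the more you have, the faster you get more" is the hypothesis).

## The model in brief

Each individual starts with `K = 0` contacts and gains them as a
pure-birth Markov chain with rate

```
f_k = 1 + τ k ,        PA  ⇔  τ > 0 ,
```

over a random activity period with a phase-type distribution: start in
phase `a` with probability `ν_a`, move to a later phase `b` at rate
`Q_{a,b}`, stop at rate `μ_a`. Time is in units of the base contact rate,
so an `m`-phase model has `(m−1) + m + m(m−1)/2` parameters, plus `τ`
with PA. The implied degree distribution `d_k` is computed exactly by a
triangular spectral recursion (cost `O(m² k_max)`, no quadrature, no
matrix inversion), zero-truncated to match surveys that cannot contain
zero-contact respondents, and fed into a multinomial likelihood.
Estimation is multi-start simulated annealing; model selection is
AIC/BIC/likelihood-ratio tests across `(phases, PA)`; uncertainty is
nonparametric and parametric bootstrap. A moment diagnostic reports
whether the fitted attachment strength makes degree moments diverge
(`r`-th moment diverges iff `r τ ≥ M_a` for some reachable phase `a`,
with `M_a` the total exit rate) — the property that decides whether
untargeted vaccination can control an epidemic on the network.

## Worked example

Simulate a survey-sized dataset from a two-phase model with genuine
attachment (`τ = 0.05`), then ask the package whether PA is there:

```r
library(patest)

truth <- pa_model(phase_type(nu = c(0.6, 0.4), mu = c(0.3, 0.12),
                             Q = matrix(c(0, 0.2, 0, 0), 2, byrow = TRUE)),
                  tau = 0.05)
y <- simulate_counts(truth, 10000, seed = 1)
#> Contact-count data: n = 8222 respondents, 175 distinct degrees, max degree 476

tab <- selection_grid(y, m_max = 2,
                      fit_settings(seed = 1, n_starts = 5, sann_iter = 1500))
print(tab)
#> Model selection over (phases, PA); n = 8222 respondents
#>  (Phases,PA) Params    logLik    dAIC    dBIC Diverge
#>       (1,No)      1 -29070.68 2652.10 2624.04       -
#>      (1,Yes)      2 -27764.64   42.02   20.98       2
#>       (2,No)      4 -27839.57  195.87  188.86       -
#>      (2,Yes)      5 -27740.63  [0.00]  [0.00]       3
```

Both AIC and BIC land on the generating model class, two phases with PA
(bracketed zeros). The likelihood ratio test of PA at `m = 2` agrees:

```r
fits <- attr(tab, "fits")
lrt(fits[["2N"]], fits[["2Y"]])
#> Likelihood ratio test: statistic = 197.87, df = 1, p = < 2.2e-16

fits[["2Y"]]$model$tau                      # attachment coefficient
#> 0.0414
1 - pa_contribution(fits[["2Y"]])           # contacts attributable to PA
#> 0.37                                      # i.e. mean drops to 63% at tau = 0
lowest_divergent_moment(fits[["2Y"]]$model, 10)
#> Lowest divergent degree moment: r = 3
```

The fitted model attributes 37% of contacts to the attachment mechanism,
and its second moment is finite (the first divergent moment is the
third): strong PA, but not the kind that makes epidemics uncontrollable.
Add `bootstrap_ci()` for confidence intervals and
`parametric_bootstrap_band()` for an uncertainty envelope around the
predicted degree distribution.

Real data go in as a `degree,count` CSV or one raw degree per line
(`read_counts()`); zero degrees are rejected because the likelihood is
zero-truncated.

## Command line

A thin CLI over the same functions ships with the package:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "patest", package = "patest"))')
$cli simulate --phases 2 --nu 0.6,0.4 --mu 0.3,0.12 --Q 0.2 --tau 0.05 \
     --n 10000 --seed 1 --out sim.csv
$cli select sim.csv --max-phases 2 --seed 1
$cli fit sim.csv --phases 2 --bootstrap 200 --seed 1 --out fit.json
$cli diagnose --phases 1 --mu 0.05 --tau 0.02
```

All JSON reports embed the seed and full resolved settings and validate
against schemas shipped in `inst/schema/`, so any run can be replayed.

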