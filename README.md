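# fontanlist

Decision support for timing the heart-transplant listing of patients with a
failing Fontan circulation, for cardiologists and decision modellers who
want an objective, reproducible benchmark beside clinical judgement.

Survivors of the Fontan palliation eventually face circulation failure and
transplant assessment. Listing too early subjects a stable patient to a
high-risk operation and lifelong immunosuppression; listing too late means
transplanting a patient whose state has deteriorated, or losing them on the
waiting list. Because the transplant is irreversible, deferral stays open,
and the outcome is uncertain, the listing choice is a *real option*, and
the optimal policy is a pair of thresholds on the patient's clinical
status.

## The model in brief

At each review the patient's comorbidity checklist is scored into a net
signal count *k* = (Good-indicative signals) − (Bad-indicative signals).
With signal quality θ (the probability a signal correctly reflects the true
post-transplant outcome) and a symmetric prior, the belief in a Good
outcome is

  p(k) = (1−θ)^k / (θ^k + (1−θ)^k).

Dynamic programming over the arrival of further comorbidities (rate μ per
year, discount rate r) yields closed-form belief bounds: the upper bound

  p_H = [ Ψ·(L_T/(L_NT−δ) − 1) + 1 ]^{−1},

with Ψ a ratio built from the smaller root β₁ of
β² − ((r+μ)/μ)β + θ(1−θ) = 0, and a lower bound p_L in closed form. Mapped
to the count scale these give thresholds k_H and k_L, and the three-way
rule:

* k ≥ ⌈k_H⌉ — **too well** for now, reassess later;
* ⌈k_L⌉ ≤ k ≤ ⌊k_H⌋ — **list**;
* k ≤ ⌊k_L⌋ — **too unwell**: do not list, or delist.

Here δ is the expected wait on the list, L_T the post-transplant life
expectancy and L_NT the life expectancy without transplant
(δ < L_NT < L_T). The package computes the thresholds, verifies them
against the regional value functions and against an independent
free-boundary lattice solver, simulates patient trajectories to evaluate
policies, sweeps parameters, and estimates θ from historical outcome
records. See the methods vignette (`vignettes/listing-windows.Rmd`) for the
full account, including two subtleties of the value-matching algebra that
the implementation makes explicit.

## Worked example

A patient developing μ = 2 comorbidities per year, θ = 80% signal quality,
r = 10% discounting, δ = 0.5 years expected on the list, L_T = 10 and
L_NT = 2 years:

```r
library(fontanlist)
params <- fontan_params(mu = 2, theta = 0.8, r = 0.1, delta = 0.5,
                        LT = 10, LNT = 2)
listing_thresholds(params)
#> Listing thresholds
#>   beta1 = 0.1850  beta2 = 0.1524  Psi = 10.2256
#>   pH = 0.0170  pL = 0.5618
#>   kH = 2.93 (floor 2, ceil 3)
#>   kL = 0.18 (floor 0, ceil 1)
#>   list while k in [1, 2]; too well at k >= 3; too unwell at k <= 0
```

So this patient should be listed while his net count is 1 or 2, is too
well to list at 3 or more, and too unwell at 0 or fewer. Scoring the
bundled example checklist (five Good- and five Bad-indicative signals,
k = 0) against these thresholds:

```r
cl <- read_checklist(system.file("extdata", "checklist_table1.csv",
                                 package = "fontanlist"))
cl
#> Checklist assessment: 10 signals (5 good, 5 bad), k = 0
decide(cl$k, listing_thresholds(params))
#> [1] "TooUnwell"
```

Monte Carlo policy evaluation (discounted life-years; the threshold policy
against the never-list baseline, whose value is the discounted L_NT ≈ 1.81):

```r
ev <- evaluate_policy(params, listing_thresholds(params),
                      n_reps = 1000, horizon = 10, seed = 1)
sprintf("%.3f +/- %.3f", ev$mean, ev$se)
#> [1] "3.444 +/- 0.076"
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fontanlist.R", package = "fontanlist"))') \
  thresholds --mu 2 --theta 0.8 --r 0.1 --delta 0.5 --lt 10 --lnt 2
#> kH = 2.93  kL = 0.18
#> listing window: [1, 2]  (too well at k >= 3, too unwell at k <= 0)
```

Subcommands: `thresholds`, `decide` (score a checklist file), `sweep`
(sensitivity CSV + plot), `simulate` (policy evaluation), `estimate`
(signal quality from an outcome-records CSV). Every run writes a JSON
manifest (parameters, seed, versions) to `--out-dir`.

Checklist files are CSV or JSON with columns `symptom`,
`observed` (`yes`/`no`/`na`) and `orientation` (`good`/`bad`); the
orientation qualifies the row *as observed*, so each assessed row
contributes one oriented signal and `na` rows contribute nothing.
Parameter configs are JSON objects with `mu`, `theta`, `r`, `delta`,
`LT`, `LNT` and an optional `review_interval_years` rescaling.

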