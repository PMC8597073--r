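---
title: "Listing windows for the failing Fontan: model, thresholds, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Listing windows for the failing Fontan: model, thresholds, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontanlist)
```

## The decision problem

Patients with a failing Fontan circulation are referred for heart-transplant
assessment, and the timing of listing is the lever the cardiologist
controls. Listing too early exposes a relatively stable patient to a
high-risk operation and lifelong immunosuppression; listing too late risks
a transplant performed in a poor clinical state, or death on the waiting
list. Because listing-and-transplanting is irreversible, deferral is
flexible, and the post-transplant outcome is uncertain, the decision is a
real option: watchful waiting has value, and the optimal policy is a pair
of thresholds rather than a single cutoff.

`fontanlist` implements that threshold policy. The observable input is a
comorbidity checklist scored at each review: every assessed item
contributes one signal oriented toward a Good or a Bad post-transplant
outcome, and the sufficient statistic is the net count `k` (Good-indicative
signals in excess of Bad-indicative ones, `k = n - 2b`). The decision rule
is three-way:

* `k >= ceiling(kH)` — too well to list for now; reassess later;
* `ceiling(kL) <= k <= floor(kH)` — list;
* `k <= floor(kL)` — too unwell; do not list, or remove from the list.

## Parameters

| symbol  | meaning                                             | units     | worked example |
|---------|-----------------------------------------------------|-----------|----------------|
| `mu`    | comorbidity arrival (clinical decline) rate         | per year  | 2              |
| `theta` | signal quality: P(signal reflects the true outcome) | —         | 0.8            |
| `r`     | discount rate on future life-years                  | per year  | 0.1            |
| `delta` | expected wait on the list before an organ           | years     | 0.5            |
| `LT`    | post-transplant life expectancy (Good outcome)      | years     | 10             |
| `LNT`   | life expectancy without transplant                  | years     | 2              |

The model requires `delta < LNT` (a patient must be expected to survive the
wait) and `LNT < LT` (transplant must offer a substantial gain), `theta`
strictly inside (0, 1) and away from 1/2, and fixes the prior belief at
one half. `mu` is patient-specific and read off the recent history; when a
unit's review interval is not one year, `read_params_json()` rescales a
per-interval count to the canonical per-year rate at load time. All of
this is enforced by `fontan_params()`, which rejects violations by naming
the assumption.

## From counts to beliefs and thresholds

With the symmetric prior, the posterior probability of a Good outcome
depends on the checklist only through `k`:

$$p(k) = \frac{(1-\theta)^k}{\theta^k + (1-\theta)^k},$$

computed by `posterior_good()` (on the log scale, so large |k| is safe) and
inverted by `k_from_p()`. The package keeps a deliberately redundant
brute-force route, `brute_force_posterior()`, which applies Bayes' rule to
the full binomial likelihoods; the two routes agree exhaustively for every
checklist up to n = 12 in the test suite. Once a patient is listed the
orientation of further decline flips (a new comorbidity now signals a Bad
outcome); algebraically this interchanges theta and 1 - theta, and the
Good-outcome probability becomes the complement `1 - p(k)`
(`listed_posterior_good()`).

`listing_thresholds()` runs the closed-form pipeline: the smaller root
`beta1` of the characteristic quadratic of the waiting recursion, the
threshold ratio `Psi`, the upper belief bound `pH`, and the lower bound
`pL`, each mapped to the count scale (`kH`, `kL`, with the inverted ratio
on the lower side reflecting the listed-region interchange). For the
worked example this gives `kH = 2.93`, `kL = 0.18`, hence the window
`[1, 2]`:

```{r}
th <- listing_thresholds(example_params())
th
```

Reports round to two decimals; full precision is retained internally.
Boundary ties are resolved by the region definitions: an exactly integer
`kH` classifies as List, an exactly integer `kL` as TooUnwell. If a
parameter set yields `kL >= kH`, the constructor refuses with a "no
listing window" diagnostic rather than returning an empty region silently.

## Value functions and where the thresholds come from

The net-count line carries six regional values: the immediate-listing
value `vr1(k) = (1 - p(k)) LT + (delta - LNT)`; the waiting-option value
`vr2(k) = A beta1^k / (theta^k + (1-theta)^k)`, which decays to zero deep
in the waiting region; the one-step bridge `vr3`; the listed values
`vr4 = vr1 + vo4` and `vr5 = vr1 + vo5`, whose option terms price
delisting; and the delisted value `vr6 = LNT`. The one-step transition
coefficients `q_down = 2p\theta + 1 - \theta - p` and
`q_up = p + \theta - 2\theta p` are genuine probabilities summing to one:
they are the chances that the next signal is Good- or Bad-indicative given
the current belief.

The thresholds are pinned by value matching: at the upper boundary the
immediate-listing value meets the waiting value (two conditions, one of
which determines the constant `A`); at the lower boundary the listed value
nets out to `LNT` (and a matching condition determines `B`).

Two structural facts about this system, established while building the
package, shape the implementation and deserve a careful statement:

1. **The matching algebra lives on the interchanged scale.** The
   closed-form bounds solve the printed regional system exactly when the
   conditions are evaluated at the interchanged net count, i.e. at `-kH`
   and `-kL`. This is the belief interchange made concrete: since
   `p(-k) = 1 - p(k)`, negating the argument is precisely the
   theta/(1-theta) swap the listed region prescribes. Evaluated naively at
   `+kH`, `+kL`, the printed forms do not match — the residuals are O(1) —
   and no constant-rescaling repairs this; the interchange does, exactly
   and for every valid parameter set, not just the worked example.
2. **On the lower side the option premium enters the indifference with a
   minus sign.** The exact identity behind the closed-form `pL` is
   `LNT + vo5 = vr1` at the boundary: the value of remaining listed equals
   the delist payoff plus the foregone option premium. The package
   implements the residual layer this way and `boundary_residuals()`
   returns all four signed residuals; they vanish to machine precision
   (well under the 1e-9 the tests demand) for the worked example and for
   seeded random parameter draws. Relatedly, the solved waiting-option
   constant `A` is negative on the interchanged scale — the option-scale
   positivity one would expect from the textbook version of this argument
   does not survive the interchange, while `B > 0` does. The package
   asserts what is actually true rather than what would be convenient.

`solve_constants()` solves `A` and `B` from one condition each (both
linear), leaving the other two conditions as the verification surface.

## The lattice oracle

`solve_prelisting()` and `solve_listed()` recover the thresholds
numerically without touching the closed forms for `beta1`, `Psi`, `pH` or
`pL`, providing an independent check of the whole algebraic pipeline. The
waiting-region value is computed by fixed-point value iteration of the
one-step recursion on a lattice tail (60 points by default) with the
decay-at-infinity condition imposed at the far end; the Bellman operator is
a contraction with modulus `mu/(r+mu)`, and the recorded sup-norm changes
decay at least geometrically at that rate. The free boundary is then
located by root-finding on the value-matching defect. Recovered continuous
thresholds agree with the closed forms to ~1e-7 and the floored integer
edges match `floor(kH)` and `floor(kL)` across seeded random parameter
sets; widening the lattice does not move them.

A design note: a naive `max(stop, continue)` value iteration is *not* a
valid oracle here. Because the stop payoff tends to `LT + delta - LNT` as
the count grows, stopping would dominate everywhere deep in the "too well"
region, so the printed thresholds are value-matching boundaries of a
boundary-value problem rather than edges of a variational-inequality
solution; an obstacle-problem iteration lands its band edges elsewhere for
most parameter sets. The free-boundary formulation is the numerical method
that matches the model's actual mathematical structure, which is why the
oracle is built that way. Convergence tolerance is 1e-12 in the sup norm
with a 200,000-sweep cap, both configurable in `lattice_problem()`;
non-convergence is an error reporting the last sup-norm change, and ties
at the edge classify as stop, consistent with the decision rule's boundary
precedence.

## The trajectory simulator

`simulate_trajectory()` realizes the generative story: a latent outcome
drawn once with probability one half; Poisson(`mu`) signal arrivals, each
matching the latent outcome with probability `theta`; and a fixed semantic
convention — a Good-indicative signal always moves `k` up. The derivation
flips the clinical interpretation of a comorbidity between the unlisted
and listed regions, and a single generative law cannot honour both flips
at once; the simulator therefore keeps signal semantics fixed and lets the
region formulas apply their own interchange. Under this convention the
Bayes-consistent belief attached to the path is `listed_posterior_good(k)`,
and marginalizing the latent outcome reproduces exactly the transition
coefficients `q_down`, `q_up` of the value recursion — the simulator's
fidelity anchor, tested at 10,000 pooled events within three standard
errors. The pooling across trajectories matters: within one trajectory the
latent outcome is fixed and the one-step rate is `theta` or `1 - theta`;
the belief-weighted mixture only emerges across fresh latent draws, and
the net count is sufficient for the latent outcome, which is what makes
pooling by current `k` correct.

Timing and mortality follow the model's own quantities. The no-transplant
life expectancy acts as a global death clock: a patient not transplanted
within `LNT` of first assessment dies then — waiting unlisted, delisted,
or still on the list (this is exactly why `delta < LNT` is assumed). The
organ wait is exponential with mean `delta` by default (the model states
only the mean; the memoryless choice adds no structure), with a fixed
delay available. Transplant succeeds with probability equal to the
listed-region belief at the transplant instant; success grants `LT`
further years, failure is immediate death. A pre-listing TooUnwell
assessment is not absorbing — the rule is reapplied as status evolves —
whereas delisting after listing is terminal. Discounted life-years
integrate survival at rate `r` from first assessment.

`evaluate_policy()` replicates trajectories with per-replicate seeds
derived from the master seed (reproducible and order-independent) and
reports the mean, Monte Carlo standard error and terminal-state tally. At
the worked-example parameters with 5,000 replicates and a 10-year horizon
guard, the threshold policy clearly beats never listing (which realizes
the discounted value of `LNT`) and edges out indiscriminate immediate
listing: the window both captures expected-value-positive transplants and
filters out low-belief ones. These problem sizes (10,000 pooled events;
5,000 replicates per policy) keep the full suite comfortably fast while
leaving the Monte Carlo error an order of magnitude below the effects
being tested.

What the simulator does not emulate: organ-allocation queues and
urgent/routine priorities, competing non-cardiac risks, continuous-severity
symptoms, or calibration to registry data. Passing its tests shows the
package's internal consistency between the generative law, the belief
algebra and the policy — not clinical validity on real patients.

## Sensitivity and estimation

`sweep_thresholds()` recomputes thresholds from scratch per grid point (no
incremental shortcuts — clarity over speed at this scale) and issues
monotonicity verdicts. Around the worked example: `kH` rises with the
expected wait `delta` and the decline rate `mu`, and falls with `LNT`;
the integer delisting edge `floor(kL)` is constant across the delta grid
(0.1–1.9 years) and the mu grid (0.5–6 per year) even though the
continuous `kL` moves slightly. Across a wide `LNT` grid (1–6 years) the
delisting bound eventually leaves (0, 1] — those points are skipped with a
warning (or fatal in strict mode) — and `floor(kL)` does move within the
valid range, so constancy there is not asserted.

`estimate_signal_quality()` implements the proportion-correct recipe: a
signal's quality is the share of exposed patients whose outcome matched
the signal's orientation, and the composite theta is the exposure-weighted
mean of the per-signal proportions — the simplest consistent composite,
isolated in one function so alternatives can be swapped.
`simulate_estimation_records()` generates records in which a signal is
present with probability theta when the outcome matches its orientation,
which under the one-half prior makes the estimator exactly consistent;
recovery at 2,000 simulated patients is within ±0.03 of a true 0.8.

## Decisions on open points

* The prior is one half at every assessment: the closed-form belief map is
  the reduction of Bayes' rule under that prior, and reassessments rescore
  the full current checklist rather than carrying a belief forward.
* The checklist length may differ between reviews; the reader accepts any
  `n` per assessment.
* A high-antibody state counts once, as a checklist signal; any associated
  lengthening of the expected wait is the user's responsibility through
  `delta` (transplant coordinators personalize that estimate anyway).
* Weighted comorbidities are expressed by entering associated sub-signals
  as separate checklist rows, never by per-entry weights.
* Degenerate inputs are rejected loudly: `theta = 1/2` (undefined count
  mapping), `delta >= LNT`, `LNT >= LT`, belief bounds outside (0, 1],
  and `kL >= kH` all name the violated assumption.

## Limitations

The model is risk-neutral by design (an objective benchmark should not
encode an individual clinician's risk appetite), treats `theta` as a
single holistic quality, does not separate urgent from routine lists, and
does not address combined heart–liver listing. The simulator's mortality
model realizes life expectancies as deterministic clocks, which is the
bluntest reading consistent with the model's payoffs; replacing it with a
survival model calibrated to registry data would be the natural next step
before any clinical use.
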