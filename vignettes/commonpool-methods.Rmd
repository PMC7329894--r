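---
title: "Methods: simulating a common-pool resource game under three choice systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a common-pool resource game under three choice systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commonpool)
```

## The resource game

`commonpool` simulates a repeated common-pool resource dilemma. A group
of $n = 4$ members harvests from a stock that starts at $R_1 = 160$
units. Each period every member $i$ extracts $e_{i,t}$ whole units; the
remainder regenerates by a growth factor $g = 2$ up to a ceiling equal
to the original stock:

$$R_{t+1} = \min\!\big(g\,(R_t - \textstyle\sum_i e_{i,t}),\; 160\big).$$

If the group removes exactly half of the stock, the stock is constant.
The equal per-member rate that exactly sustains the stock is therefore

$$r^\ast = \frac{100\,(1 - 1/g)}{n} = 12.5\%$$

of the current stock per member and period — the benchmark against
which all extraction behaviour is judged (`sustainable_rate()`).
Extracted units are worth 0.01 EUR each; a session lasts 6 periods per
choice system and the stock resets to 160 units at the start of each
system, never within one.

**Caps.** In *symmetric* groups every member may take up to 1/4 of the
current stock. In *asymmetric* groups two *advantaged* members may take
up to 1/3 and two *disadvantaged* members up to 1/6. Requests are whole
units, so fractional caps are floored (`extraction_limit(160,
"advantaged")` is 53). Whether the original software floored or rounded
is unknown; flooring is the conservative convention and is documented
rather than claimed as the original behaviour.

**Exhaustion.** A stock below one unit is exhausted; remaining periods
are recorded with all-zero extractions (sessions always run their full
length). With integer requests and the doubling law the stock is always
an integer, so exhaustion means exactly zero units.

## The three choice systems

* **Individual choice** — members decide simultaneously and
  independently, bounded by their cap.
* **Median choice** — each member states a desired own level; the mean
  of the two middle order statistics of the four proposals is imposed
  on everyone identically (`resolve_median()`). The common level may
  exceed a disadvantaged member's own cap; such periods carry an
  override flag. Because each proposal respects its proposer's cap, the
  implemented level can never overdraw the stock: the middle-two mean
  is at most $(R/6 + R/3)/2 = R/4$ in asymmetric groups and at most
  $R/4$ in symmetric ones.
* **Majority voting** — each member proposes a full per-member
  allocation; identical allocations are pooled (`pool_identical()`);
  every member casts one mandatory ballot; an allocation with at least
  3 of 4 votes is implemented exactly, otherwise each member extracts
  individually (`tally()`, `resolve_majority()`). With four single
  votes at most one option can reach the threshold, so no tie-break is
  needed at the electing margin.

Two conventions the protocol leaves open are made explicit and
switchable: allocations inside voting proposals respect each target
member's cap (`enforce_caps_in_proposals`, default on, which keeps the
mechanisms comparable), and proposal identity is component-wise
equality under the stable internal member ordering (the experiment's
display-side shuffling of member numbers is an anonymity device, not
part of the mechanism, and is not simulated).

## The synthetic participants

The original study used human participants; their decision rules are
unobserved. The generator in `behavior_params()` /
`sample_population()` is a declared synthetic stand-in whose role is to
reproduce the statistical structure of the published cell summaries, so
that the entire analysis pipeline can be exercised end to end. What
passing tests show is that the *pipeline* recovers what the *generator*
put in — not that humans behave like the generator.

The behaviour model, with every parameter exposed:

* **Target rates.** Person-level target extraction rates (percent of
  the current stock) are drawn per system-by-role cell from a clamped
  normal. Defaults: individual choice 13.46 / 17.44 / 12.92 for
  symmetric / advantaged / disadvantaged (SD 5.2) — the role values are
  the published per-role individual-choice rates, and the symmetric
  value is implied by the published overall individual-choice mean of
  14.46 with 104 symmetric and 144 asymmetric participants; median
  proposals 13.32 (SD 1.49) for all roles (the rule equalises outcomes
  anyway); voting fallback 13.0 / 16.5 / 12.5 (SD 3.6). Person effects
  mix a shared and a system-specific standard-normal draw (weight 0.8),
  which puts the person-level intraclass correlation of the average
  percentage taken near the published 0.25. The distribution family is
  a choice — only means and SDs are published.
* **Period decisions.** Request = rate + within-person noise (SD 2 / 1
  / 2 percentage points by system), applied to the current stock,
  rounded to whole units, clamped to the cap. In the final period a
  member grabs the full cap with probability 0.6 (an end-game effect:
  sustaining the stock no longer pays; the published data show heavy
  period-6 depletion but do not identify the individual mechanism, so a
  Bernoulli cap-grab is the simplest stand-in).
* **Voting proposals.** With probability `cooperativeness` a member
  proposes the equal split at the sustainable rate (feasible for every
  role, as 12.5 < 16.7); otherwise a self-favouring allocation raising
  the own rate by 6 points and lowering the others' by half the
  compensating amount — self-favouring proposals are therefore also
  greedier on average, mirroring the published pattern that non-elected
  proposals had both higher mean rates and much higher between-member
  variation. Cooperativeness defaults to 0.71 (symmetric) and 0.58
  (asymmetric): under the own-payoff-maximising vote rule a proposal is
  elected exactly when at least three members propose the identical
  equal split, so the per-period election probability is
  $4c^3 - 3c^4$, and these values reproduce the published
  voting-success means (about 3.35 vs 2.20 of 5, overall 2.69,
  condition gap about 1.15). They were derived from that closed form,
  not tuned against simulation output.
* **Ballots.** A member votes for the pooled proposal maximising their
  own allocated units; ties break toward the lower between-member
  spread, then the earliest submission. Alternative vote rules
  (distance to own preference) are out of scope.
* **Ratings.** After each system, six 1–7 items are drawn from a latent
  normal: system base means 4.12 / 5.03 / 4.82 (individual / median /
  voting), a 0.43 symmetric-vs-asymmetric gap, a 0.27
  advantaged-vs-disadvantaged gap, a person effect (SD 0.9), an item
  residual (SD 1.2), and — for the voting system — a slope of 0.38 on
  the group's voting success count centred at 2.69. The success slope
  is what gives the synthetic cohort its mediation structure
  (asymmetry lowers success, success raises ratings). One group's
  voting-rating block is dropped with probability 1/62, emulating the
  study's technical loss of one group, so the pipeline must tolerate
  missing blocks.

What the generator does **not** emulate: time trends across periods
within a system (beyond the end-game grab), order effects between
systems (the order position is recorded but does not shift behaviour),
social value orientation, learning, or any coordination between
members beyond the mechanisms themselves. Results that depend on those
features of real data are outside what this simulation can show. Early
exhaustion (before period 6) is rarer in the synthetic cohort than in
the study's tail cases.

## The analysis pipeline

All statistics operate on tidy long tables (`run_experiment()`, CSV
round-trip via `write_dataset()` / `read_dataset()`).

* **Percentage taken** — $100\,e_{i,t}/R_t$, undefined when the stock
  is exhausted. Averages (`average_percentage()`) use periods 1–5: the
  sixth period is a different decision situation and is excluded, as in
  the original analysis. Exhausted periods yield missing percentages
  and are excluded by default (`exhausted_policy = "exclude"`; the
  original handling is not documented, so the policy is a flag).
* **Profits** — unit value times summed extraction over the window.
* **Voting analytics** — per-group success counts (0–5); per-proposal
  features: mean rate, absolute deviation from 12.5, and the
  between-member *sample* SD of the four rates (the published
  dispersion measure is unnamed; the sample SD with $n-1$ is our
  documented choice). The election logit is a maximum-likelihood
  binomial GLM (IRLS, tolerance $10^{-8}$, at most 100 iterations,
  intercept included, features untransformed), with odds ratios
  $e^b$ and a separation diagnostic. On the synthetic cohort the vote
  rule makes election nearly deterministic in the spread, so that fit
  is close to separation by construction; coefficient recovery is
  instead validated on data simulated from a logistic model with the
  published coefficients.
* **Reliability** — Cronbach's $\alpha$ from the defining variance
  formula and a one-way random-effects ICC from the ANOVA
  decomposition (unbalanced groups handled via the standard $k_0$
  correction, estimates truncated at zero).
* **Composite ratings** — the mean of the six items; the greed item is
  *not* reverse-coded by default (the original scaling is not
  documented; `reverse_greed` switches it), and a missing block yields
  a missing composite.
* **Mediation** — path $a$ (success on condition contrast), path $b$
  (composite on success, condition-adjusted, since the published
  account is of *partial* mediation), indirect effect $= a \times b$
  exactly, percentile CI over case-resampled bootstrap replicates
  (default 5000, seeded).
* **Trajectory projections** — `project_trajectory()` iterates the
  exact regeneration law at a constant equal rate with no intermediate
  rounding and reports exact and rounded end stocks. At 12.92% the
  160-unit stock holds 130 units (exact 130.34) after six periods; at
  12.5% it is a fixed point at 160 for any horizon.
* **Contrast coding** — dummies for median choice and majority voting
  (individual choice as reference), Asymmetry $\pm 0.5$ (symmetric
  negative), Advantaged $\pm 0.5$ within asymmetric groups and 0 for
  symmetric participants. Multilevel mixed models themselves are
  deliberately not re-implemented: the pipeline emits the model-ready
  table for standard mixed-model tooling, and the workflow scripts
  check only effect directions on synthetic data.

## Numerical conventions

Extraction requests are integers; the median rule can produce
half-integer levels (mean of two middle integers), so stocks and
extractions are carried as exact reals internally. Payoffs are rounded
half-up to cents at the final step only. The sustainable-rate
derivation in the acceptance script lifts the regeneration ceiling
before root-finding, because with the cap in place every rate at or
below 12.5% fixes the stock and the root is not isolated. All
stochastic entry points take explicit seeds; the engine itself is
deterministic given the decisions.

## Problem sizes used in the checks

The test suite simulates cohorts of 6–8 groups for invariant checks and
the full 62-group cohort in the workflow scripts; parameter-recovery
checks use 250 groups (1000 participants), the election-logit recovery
5000 proposals, the ICC recovery 500 groups of 12, and the mediation
coverage check 200 repetitions of 60 cases with 400 bootstrap
replicates each. These sizes give Monte-Carlo error comfortably inside
the asserted bands while keeping the default run quick.
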