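---
title: "Probabilistic and dynamic grading of slope ecological restoration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic and dynamic grading of slope ecological restoration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopeval)
```

## The model

A *grade standard* assigns each evaluation index one half-open value
interval `(lo, hi]` per quality grade (I best … V worst), or, for
ordinal indexes, the fixed scores 1…5. The standard is the only place
expert judgement enters; no index weights exist anywhere in the method.

One Monte-Carlo trial materializes the standard as five
*representative objects*: the grade-g representative draws every
quantitative index uniformly from its grade-g interval and sets every
ordinal index to score g. The investigated site is then assigned the
grade of the representative with the largest sqrt-cosine similarity

$$\mathrm{sim}(a,b) \;=\;
\frac{\sum_j \sqrt{a_j b_j}}{\sqrt{\sum_j a_j}\,\sqrt{\sum_j b_j}},$$

the cosine of the angle between $\sqrt{a}$ and $\sqrt{b}$ (a Hellinger
affinity). It lies in $[0,1]$, equals 1 exactly for proportional
vectors, and is invariant to rescaling *both* vectors by one positive
scalar. The summation runs over **all** indexes of the standard.
Repeating the trial $N$ times gives grade probabilities
$P(k) = \mathrm{Num}_k/N$; the modal grade is the evaluation result.

Because the trial fractions are exact, $\sum_k P(k) = 1$ holds by
construction — the test suite asserts it over randomly generated
standards rather than trusting the bundled one.

### Dynamics

The probability vector is read as a Markov state and projected by
$X_{r+1} = X_r P$ with a row-stochastic $5\times 5$ transition matrix.
Two modeling assumptions shape $P$:

* transition probabilities between states are free parameters (no
  equality structure is imposed; an exactly uniform fitted row is
  admissible and merely flagged in diagnostics);
* the certain-best state $(1,0,0,0,0)$ and certain-worst state
  $(0,0,0,0,1)$ never change. This is implemented as hard absorbing
  constraints $P_{11}=P_{55}=1$ (rows 1 and 5 are unit vectors),
  toggleable via `absorbing_endpoints` and ON by default, which makes
  the fixed-point property hold by construction.

Lacking multi-year panel data, $P$ is estimated from sparse
*calibration* distributions $S(r)$ observed after $r$ transfer steps by
minimizing the summed relative deviation

$$Q \;=\; \sum_r \sum_k
\left|\frac{S_k(r)-\hat S_k(r)}{S_k(r)}\right|,
\qquad \hat S(r) = X_0 P^r,$$

subject to row sums 1 and non-negative entries.

### Index sensitivity

Local sensitivity of a scalar output functional $F$ to index $i$ is the
one-sided finite difference normalized to relative changes,
$S_i = |(\Delta F / F) / (\Delta x_i / x_i)|$. The output functional is
deliberately configurable (see below) because the method's raw output is
a probability vector, not a scalar.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_trials` | 1000 | trials | estimates are stable beyond ~1000 trials for the bundled application; binomial error of a mid-range probability is ±1.6 points |
| `seed` | 42 (CLI) | — | full reproducibility end to end; library calls may pass `NULL` to use the ambient stream |
| `normalize` | `FALSE` | — | raw index values reproduce the bundled engineering results; the flag divides each index by its largest standard bound when scale balance is wanted |
| `absorbing_endpoints` | `TRUE` | — | encodes the stated fixed-point property of certain-best/worst states |
| `restarts` | 16 | starts | the objective is non-convex for $r>1$; multi-start local search with a uniform-interior start included |
| `epsilon` | 1e-6 | probability | safeguard replacing zero observed $S_k(r)$ in the denominator, keeping those terms finite (≈ absolute deviations at scale ε) |
| `delta` | +2 | index units | the stated index-uncertainty standard deviation; also the sd of the Normal-draw variant |
| `functional` | `modal_prob` | — | the headline output (probability of the base modal grade); alternatives below |

## What the synthetic generator emulates

`random_grade_standard()` mimics the structure of real grading tables:
contiguous half-open intervals from gamma-distributed gaps on scales
spanning roughly 1–300, both grade directions, and a ~20% share of
ordinal indexes (the bundled standard has 3 of 15). `random_object()`
optionally draws a *true grade-k specimen* for parameter-recovery
checks.

It does **not** emulate correlated indexes, measurement error, or
standards with gaps between grade intervals. A green property test
therefore establishes the contracts (normalization, reproducibility,
in-interval sampling, recovery on well-separated standards) — not that
the method discriminates neighboring grades on any particular real
standard. That discrimination is exactly what `separation_diagnostic()`
measures per standard.

## Numerical choices

* **Boundary convention.** Membership is `(lo, hi]`: a shared endpoint
  belongs to the interval where it is the upper bound. Uniform sampling
  does not distinguish the open end (measure zero).
* **Ties.** Exact similarity ties resolve to the most favorable grade
  and set a `tie` flag. Under continuous sampling ties have probability
  zero; any fixed rule works, this one is documented.
* **Out-of-range observations** are accepted with a warning:
  classification never bins the target value, so they are mathematically
  admissible. `grade_of_value()` returns `NA` for them. Ordinal scores
  outside 1…5 are rejected.
* **Contiguity** of grade intervals is enforced by validation; every
  published index is contiguous. (The extreme "widely separated grades"
  case used by the separation tests is hand-assembled precisely because
  it cannot arise from validated input.)
* **Solver.** Free rows of $P$ are parametrized by softmax logits, so
  row-stochasticity is unconditional. Each start runs BFGS on a
  graduated smoothing of the absolute values ($\sqrt{d^2+s^2}$ with
  $s = 10^{-2}, 10^{-4}$) and finishes with two exact Nelder-Mead
  polishes; the best of 17 starts is returned, with the spread of $Q$
  across starts reported. Uniqueness of $P$ is *not* claimed — only the
  fitted trajectory is guaranteed, which is why the recovery test
  checks $Q$, not matrix entries. Matrix powers use repeated
  multiplication (steps are small integers).
* **Reporting.** Probabilities are stored at full precision and rendered
  to two decimals.

## Open design points, decided

* **The sensitivity functional.** The literature description never binds
  $F$ to a concrete output. Default: probability of the *base* modal
  grade, evaluated under common random numbers (the same seed for base
  and perturbed runs) so the difference is not drowned in Monte-Carlo
  noise. Alternatives: `midpoint_sim` (similarity to the modal grade's
  interval-midpoint representative; deterministic and noise-free) and
  `expected_grade` ($\sum_k k P(k)$). A Normal-draw variant
  (`normal_draws > 0`) replaces the fixed step with draws from
  $\mathcal N(x_i, \delta)$ truncated at zero, emulating the stated
  uncertainty model.
* **Ordinal perturbation.** Ordinal scores are perturbed on the
  continuous score scale and clipped to `[1, 5]` with a warning; a
  perturbation clipped to a zero step has no finite difference and is
  reported as skipped rather than silently dropped.
* **Batch independence.** `evaluate_batch()` derives one sub-seed per
  position from the master seed, so a target's result depends only on
  the seed and its position, never on the other targets.

## Known limitations

* **Scale dominance.** With raw values the similarity is dominated by
  large-magnitude indexes (here: available K, ~100–260 mg kg⁻¹) while
  ordinal scores of 1–5 are nearly inert — a property of the statistic,
  visible in the sensitivity rankings, where small-magnitude indexes
  essentially cannot top the list. The `normalize` flag trades
  reproduction of the bundled results for scale balance.
* **Separation is empirical.** For contiguous standards, draws near a
  shared boundary make some between-grade pair more similar than the
  least similar within-grade pair in almost every trial;
  `separation_diagnostic()` reports exactly how often. Strict separation
  requires grade-specific dominant indexes and interval gaps.
* **Saturated probabilities flatten sensitivity.** When the base
  evaluation is certain ($P \approx 1$), small perturbations flip no
  trials and finite differences vanish; the deterministic
  `midpoint_sim` functional is the workaround.
* **The fitted matrix is not identified** from a short calibration:
  many matrices reproduce the same trajectory. Conclusions should be
  drawn from projected distributions, not individual entries of $P$.
* Calibration must be supplied as explicit numeric distributions;
  deriving it from narrative monitoring descriptions is out of scope.
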