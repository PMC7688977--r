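---
title: "Federated Cox regression across cancer registries: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated Cox regression across cancer registries: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsurv)
```

## The estimation problem

Two population-based cancer registries hold one analysis row per surgically
treated first-primary oral-cavity squamous cell carcinoma: follow-up time,
a death indicator, and nine categorical covariates (country, age group,
sex, period of diagnosis, stage group, tumour location, grade, treatment,
hospital volume). Regulation prevents pooling the rows. `fedsurv` fits the
Cox proportional-hazards model on the combined cohort anyway, by exchanging
only aggregate statistics.

Follow-up is measured in years with one decimal. This is a deliberate
coarsening: it bounds the number of distinct event times $K$ (and with it
the size and number of the exchanged aggregates) regardless of cohort
size, at the cost of making tied event times ubiquitous. Ties are handled
with Breslow's approximation, which keeps the partial likelihood additive
across sites — the property the whole design rests on.

## Model and federated decomposition

Let $z_i$ be the 0/1 dummy vector of subject $i$ (one column per
non-reference level per covariate block, 18 columns for the full
specification) and $t_1 < \dots < t_K$ the distinct event times of the
whole federation. With $w_i(\beta) = \exp(\beta'z_i)$, the Breslow partial
log-likelihood is

$$\ell(\beta) = \sum_k \Big[\beta's_k - d_k \log S^{(0)}_k(\beta)\Big],$$

where, *per site and per event time*, $d_k$ counts events, $s_k$ sums the
covariates of those events, and
$S^{(0)}_k = \sum_{i: t_i \ge t_k} w_i$,
$S^{(1)}_k = \sum z_i w_i$, $S^{(2)}_k = \sum z_i z_i' w_i$ run over the
risk set. All five are sums over disjoint subjects, so the server obtains
the federation-wide quantities by element-wise addition and runs
Newton–Raphson on

$$U(\beta) = \sum_k \Big[s_k - d_k \tfrac{S^{(1)}_k}{S^{(0)}_k}\Big],
\qquad
\mathcal I(\beta) = \sum_k d_k \Big[\tfrac{S^{(2)}_k}{S^{(0)}_k} -
\tfrac{S^{(1)}_k}{S^{(0)}_k}\tfrac{S^{(1)\prime}_k}{S^{(0)}_k}\Big].$$

Each iteration is one task round-trip: the server broadcasts the current
$\beta$, nodes return $(d, s, S^{(0)}, S^{(1)}, S^{(2)})$ over the shared
grid, the server sums and updates. $d_k$ and $s_k$ do not depend on
$\beta$ and are cached after the first round (mathematically identical to
recomputing them). The covariance reported is
$\mathcal I(\hat\beta)^{-1}$, recomputed in one final round at the
converged estimate, so it is exact at $\hat\beta$ rather than at the last
pre-convergence iterate.

Censored subjects at time $t$ remain in the risk set for events at $t$
(the standard convention; subjects contribute to risk sets through the
interval in which they are censored).

## Stopping rule and numerics

* **Stopping rule.** Iteration stops when
  $\lvert\sum_j e^{\beta_j^{new}} - \sum_j e^{\beta_j^{old}}\rvert <
  10^{-8}$ — the change in the *sum of hazard ratios* between iterations.
  This criterion is implemented literally; `criterion = "max_delta"`
  (largest absolute coefficient change) is available as an alternative.
  Both vanish at a stationary point; correctness is established in the
  test suite by comparison against an independent centralized fit, not by
  the stopping metric itself. Well-conditioned fits converge in about 5
  iterations.
* **Centering.** Before iterating, one column-sums round computes the
  federated mean of each design column; nodes center their columns at
  these means. The estimate, information and likelihood are invariant to
  this shift (the centering constant cancels between $\beta's_k$ and
  $d_k\log S^{(0)}_k$); it only improves the conditioning of the
  information matrix.
* **No step-halving.** The update is plain Newton–Raphson. Non-convergence
  within `max_iter` (default 50) is an error carrying the iteration trace,
  never a silently damped step. A singular information matrix is reported
  with the names of the near-collinear columns.
* **Tie-safe time arithmetic.** Times are converted once to integer
  "deci-years" (`round(10 t)`), so floating-point representation can never
  split a tie or misalign a site's event time with the shared grid.
* **Risk-set computation.** Nodes sort once by time and use suffix
  cumulative sums, giving $O(n p^2)$ work per iteration independent of
  $K$.

## What crosses the site boundary, and the audit

Per fitting round a node returns arrays of shape $K$, $K\times p$ and
$K\times p\times p$; descriptive tasks return level-count vectors or
(sum, n) pairs. Nothing sized like the site's patient table ever leaves a
node, and `audit_payload()` enforces exactly that rule: a returned array
with any dimension equal to the site's record count fails the audit unless
that count coincides with a dimension derived from $p$ or $K$. Every
payload of every task is appended to an audit trail (optionally a
JSON-lines file) with its shapes and byte size; `audit_report()`
summarises it.

Two aggregate quantities are still shared by design and should be named:
the global event-time grid (required by the decomposition) and per-site
event counts per grid time. Both are aggregates, but a grid time with one
event at one site does reveal that *some* patient there died in that
tenth-of-a-year. The one-decimal coarsening blunts this; a production
deployment would add minimum-count thresholds, which are out of scope
here. The transport is in-process message passing (queues between node and
server objects); the contract — only `Task`/`TaskResult` objects cross the
boundary — is what the package tests, and a socket transport could be
substituted behind the same interface. Authentication is reduced to
registry membership; production security is not simulated.

## Cohort derivation choices

* **Year length and rounding.** Exact survival is days/365.25, rounded
  half-away-from-zero to one decimal (base `round()`'s round-half-even
  would treat 2.45 and 2.55 asymmetrically). Both constants are recorded
  in the run manifest so downstream users can audit them.
* **Cutoff as information horizon.** Vital-status information ends at
  2019-01-31: an end date after the cutoff — even a recorded death —
  censors the record at the cutoff.
* **First-primary rule.** Among a patient's records with
  `tumour_sequence == 1`, the earliest diagnosis wins; exact date ties are
  broken by the lexicographically smallest record id, making selection
  deterministic.
* **Unknown is a level.** Unknown stage and grade are explicit analysis
  levels with their own hazard ratios, never dropped or imputed, and they
  participate in interaction blocks like any other level.
* **Hospital volume** is computed within one registry from the retained
  (post-filter) surgeries per hospital and diagnosis year; counting
  pre-filter records instead is available behind a flag
  (`compute_hospital_volume` operates on whatever table it is given).
* **Topography matching** is prefix-based at the 3-character level for
  C02/C03/C04/C06 and exact for the enumerated C00.x/C05.x subsites, so
  soft palate (C05.1) is excluded while unsubtyped "C02" is included.
  Dates are assumed day-resolved ISO-8601; registries that record only
  month would need a documented imputation upstream.

## The synthetic generator: what it does and does not emulate

`generate_cohorts()`/`generate_registry()` draw, per country: categorical
covariates independently per variable with marginals proportional to the
published two-country frequency table; survival from a proportional-hazards
model whose default true log-hazard ratios are the log of the published
combined multivariable hazard ratios; an exponential baseline with rate
0.06/year for a reference-level patient (chosen once as a plausible scale
for a surgically treated cohort — roughly 26% baseline five-year
mortality — and kept); diagnosis dates over 2004–2016 and administrative
censoring at the 2019-01-31 cutoff. A Weibull baseline is selectable.
Hospital-volume strata are filled by largest-remainder quota and realised
as hospital-year cells (≤ 49, 50–99, ≥ 100 patients), so the derived
volume categories reproduce the configured profile exactly; a stratum that
cannot be filled at the configured cohort size (e.g. a ≥ 100 cell from 29
patients) is a hard error rather than a silent degradation. Contaminant
records violating one selection filter each can be requested to exercise
the exclusion log.

What the generator does *not* emulate: joint dependence between covariates
(only marginals; an age–stage dependence hook exists for stress tests),
calendar trends, registry-specific data-quality artefacts, or non-
proportional hazards. Passing tests therefore demonstrate correctness of
the *estimator and infrastructure* under the proportional-hazards model,
not fidelity of any synthetic cohort to the real registries — the
published hazard ratios from the real data are not reproducible from
synthetic marginals, and the package does not attempt it.

## Interaction analysis

For each prognostic factor, the reduced model is the full main-effects
specification and the full model adds the country×factor block; the
likelihood-ratio statistic $2(\ell_f - \ell_r)$ is referred to
$\chi^2_{L-1}$ for a factor with $L$ levels. The test is *joint* over the
factor's interaction columns, one factor at a time, adjusted for all main
effects — a saturated all-factors interaction model is not fitted.
Per-country hazard ratios are read off the full model relative to the
(reference level, Taiwan) cell, with delta-method intervals on coefficient
sums. Under the null the test is calibrated (rejection rate ≈ 5% at
α = 0.05 in the Monte-Carlo suite) and for a single-df interaction it
agrees with the Wald test on the interaction coefficient in ≥ 95% of
large-sample replicates. No multiplicity adjustment is applied across the
five factor tests, matching the analysis the package mirrors.

## Problem sizes used in the test and acceptance suites

Structural worked examples run on printed inputs (stage counts, a 2×2
table). Simulation checks use: oracle equivalence and partition invariance
at n = 2,000 with the full 18-column design split across 2–5 sites;
parameter recovery at n = 20,000; Wald-interval coverage over 200
replicates of n = 1,500 with two covariates; null calibration of the
interaction LRT over 500 replicates of n = 2,000; power against a 0.5
log-HR interaction over 40 replicates of n = 5,000. These sizes were
chosen to make Monte-Carlo bands decisive while keeping a full run in the
minutes range on one CPU; the NL = 1,100 / TW = 900 split of the n = 2,000
cohorts is the smallest round split at which every default volume stratum
(including the ≥ 100 cell at the NL share of 9.5%) is feasible.

## Known limitations

* Proportional-hazards diagnostics (e.g. Schoenfeld residuals) are not
  implemented, matching the system the package mirrors; fits assume the
  model.
* Efron ties, time-varying covariates, stratified baselines and
  penalization are out of scope.
* The `hr_sum` stopping rule can in principle trigger on cancelling
  coefficient movements; the oracle-equivalence tests (and the
  `max_delta` alternative) guard against this in practice.
* Comparing mean age between countries is provided only as a federated
  mean; no test statistic is attached, since none is defined for it in the
  mirrored analysis.
* The in-process transport simulates orchestration semantics (queuing,
  pickup, timeouts via offline nodes), not network failure modes.
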