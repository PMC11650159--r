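---
title: "Effort foraging: model, simulation and inference methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort foraging: model, simulation and inference methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortforage)
```

## The task and the model

In the Effort Foraging Task a participant repeatedly chooses between
*harvesting* a patch whose rewards deplete, and *exiting* to a fresh patch at
the price of an effortful travel task (an N-Back round in the cognitive
conditions, rapid key-pressing in the physical ones; each effort type is run
at a low and a high level). The orchard is parameterized by
`foraging_config()`: the first (forced) harvest of a patch pays
Normal(15, 1) apples; every later harvest pays the previous reward times a
Beta(14.90873, 2.033008) decay draw (mean 0.88), floored at 0.5 apples.

Patch leaving is modelled with the Marginal Value Theorem (MVT). On each free
trial the agent compares the expected next reward,

\[ R_{e,t} = \kappa \cdot r_{t-1}, \qquad \kappa = \frac{\alpha}{\alpha+\beta_d} = 0.88, \]

against a per-condition exit threshold \(\rho\), and harvests with softmax
probability

\[ P(\text{harvest}) = \mathrm{logit}^{-1}\!\big(\beta\,(R_{e,t} - \rho)\big). \]

The threshold is not free: it is the average net reward per harvest period
implied by the condition's own totals,

\[ \rho = \frac{\sum R - n_{\text{travel}}\, c}{T}, \qquad
   T = \frac{\text{condition duration}}{\text{harvest duration}}, \]

where \(c\) is the travel (effort) cost in apples: \(c_{\text{low}}\) in
low-effort blocks and \(c_{\text{low}} + c_{\text{high}}\) in high-effort
blocks. The *marginal* high-effort parameterization isolates the extra
subjective cost of the harder travel task from everything the two conditions
share — in particular from the large common individual differences in overall
exit thresholds. Costs may be negative (effort seeking). Totals include
forced first harvests, and rewards enter as obtained (floor-truncated); the
forced harvests themselves never enter the choice likelihood.

## Trial timings

The published task holds trial timing constant across conditions but the main
text does not state the constants. The package defaults are 3 s per harvest
and 24 s per travel within 7-minute blocks, two blocks per condition. These
are configurable (`harvest_duration`, `travel_duration`), and no analysis in
the package depends on them except through the information content of the
resulting logs: `T`, and therefore the leverage `n_travel/T` that converts
threshold shifts into apples of cost, follows from them.

## The synthetic cohort: a stated world

`simulate_cohort()` draws per-participant parameters, simulates full
sessions, and carries latent symptom factors with known structure. The frozen
generative population is

| parameter | distribution | rationale |
|---|---|---|
| \(c_{\text{low}}\) | Normal(10, 15) apples | reproduces the wide common variation in overall exit thresholds the task shows (threshold SD a few tenths of an apple once scaled by \(n/T\)), with a minority (~25%) of negative, effort-seeking costs |
| \(c_{\text{high}}\) | Normal(4, 6) apples | marginal costs clearly positive on average, spread matching the published cost histograms; ~25% effort seekers |
| \(\log \beta\) | Normal(log 3, 0.4) | steep exit curves: choices are sharply threshold-like, as in the published posterior-predictive checks |

Two points about this choice deserve emphasis. First, the identifiability of
a cost from choices is limited: the likelihood pins \(\rho\) to roughly
±0.1–0.3 apples with eight blocks of data, and costs are read off thresholds
through the multiplier \(T/n_{\text{travel}} \approx 17\), so per-participant
cost estimates carry noise of several apples *no matter how good the
sampler is*. A generative population much narrower than the above would make
truth-versus-estimate correlations of 0.7+ unattainable in principle.
Second, the model-agnostic exit-threshold estimate (below) is biased by a
softmax overshoot term of order \(2/\beta\); if \(\beta\) is small or very
heterogeneous that bias swamps real threshold differences. The defaults were
fixed on these grounds — matching the published data's visible features — and
then frozen; acceptance tolerances were never adjusted to them.

Symptom couplings are planted as
`cost = mean + sd * (b * latent + sqrt(1 - b^2) * noise)`, so `b` is the
generative standardized slope and the marginal SD is preserved.

### Self-consistent thresholds

Equation-style thresholds depend on realized totals, which depend on
behaviour. Agents therefore solve a fixed point: simulate the session at
\(\rho\), recompute \(\rho\) from the realized totals, repeat
(`solve_agent_thresholds()`, tolerance 10⁻³ apples, max 50 iterations). The
session is replayed under common random numbers with per-block and per-patch
substreams, which makes the iterated map deterministic and piecewise
constant with small jumps: a threshold change truncates or extends
individual patches rather than rescrambling the whole session. Most seeds
converge exactly; the rest settle into small cycles, in which case the best
iterate is kept and the residual reported (a warning is raised above 0.05
apples). The *final* trial log is the fixed-point session itself, so the
data realize the thresholds they were generated under — which is exactly
what the fitted model assumes.

What the generator does *not* emulate: reaction times, within-block fatigue
dynamics, travel-task stimulus streams (only summary performance measures are
carried), item-level questionnaire semantics, and any dependence of
performance on symptom severity (performance is generated independently, so
covariate adjustment in the regression battery is exercised under the null
unless a coupling is planted). A green test therefore certifies the
estimation machinery, not any claim about real participants.

## Hierarchical Bayesian estimation

No Stan-class sampler is available in the target environment, so
`fit_mvt_hierarchical()` implements MCMC directly: adaptive random-walk
Metropolis-within-Gibbs, vectorized across participants. Participant blocks
(low costs; the two marginal costs jointly; log β) are updated against the
choice likelihood; group-level means, SDs and the cost correlation are
updated against the participant draws. Group priors: Normal(0, 5) cost
means, half-Normal(2.5) cost SDs, Normal(0, 1.5)/half-Normal(1) for log β,
and a bivariate normal over the two marginal costs with an LKJ(2) prior on
their correlation — this exposes the cognitive–physical cost-correlation
posterior as a first-class estimand. Proposal scales adapt during warmup
only (Robbins–Monro toward 0.44 acceptance, 0.3 for the 2-D block); each
recorded iteration thins `sweeps = 10` internal sweeps, which buys mixing at
fixed storage. Convergence is gated on split-R-hat < 1.01 with a warning
(never silently), and point estimates are posterior means throughout.

Numerical details worth knowing:

- the likelihood is evaluated on padded matrices per condition
  (`plogis(..., log.p = TRUE)` on signed logits), so a full sweep is a
  handful of matrix operations regardless of cohort size;
- `rho` is linear in the costs given observed totals, so posterior-mean
  thresholds satisfy `rho = A - B * c` exactly at the posterior-mean costs;
- participants with fewer than `min_exits` (default 2) exits in a condition
  are dropped from that effort type with a logged reason; their other effort
  type is retained;
- `flat_priors = TRUE` removes the group level and gives bounded-uniform
  participant priors; with `fix_beta` this reduces the model to a form that
  can be validated against brute-force grid integration (the acceptance
  suite does this on a two-trial instance, agreeing to < 2%);
- the group-difference variant samples an explicit mean shift `delta` for
  every parameter (prior Normal(0, 2.5)), so diagnostic-group contrasts can
  be read inside the hierarchy rather than off shrunken point estimates.

## Model-agnostic thresholds

`exit_regression()` fits `log(R_e) ~ effort_level + (1 | participant)` on
exit trials only (lme4, random intercepts, natural log; single-participant
inputs fall back to fixed effects with a warning). Per-participant overall
exit thresholds are the exponentiated participant-level predictions from the
low-effort-conditions regression — the least effort-confounded estimate of
the subjective opportunity cost of time. Exit-trial expectations inherit the
trial-log convention: first harvests are excluded and the second-harvest
expectation is the forced harvest's reward times κ.

## Symptom scoring

`score_factors()` applies, per factor: (1) iterative corrected item-total
filtering at 0.2 — "inter-item correlation" is interpreted as the corrected
item-total statistic of the usual `item.total` utilities, removing the
single worst item and recomputing until stable, which makes the filter a
fixed point; (2) a Cronbach's alpha gate at 0.6 on the retained items;
(3) z-scoring within the scoring population (MDD-only by default, all
participants as the generalizability variant) and averaging, scoring a
participant only when at least half the retained items are present. The
published analysis computed confirmatory factor scores by exactly this
z-score-and-average rule; a fitted latent-variable model is deliberately not
substituted for it.

## Clinical statistics

`fit_spec()` standardizes every variable and reports the standardized OLS
coefficient of the predictor with its t and p, R² and adjusted R²;
complete-case analysis, no imputation. `run_symptom_battery()` fits one model
per symptom factor (seven in the canonical battery), controls
Benjamini–Hochberg FDR at 0.05 *within* the battery (family size shrinks if
a factor was excluded upstream), and offers the sensitivity variants used in
the published analysis: currently-depressed subset, medication covariate,
all-participants population, and the anxiety-adjusted battery. Effort-type
specificity uses `compare_dependent_correlations()` — the
Meng–Rosenthal–Rubin z for two correlations sharing a variable, with the
`f` factor capped at 1 — two-sided throughout.

## Known limitations

- The sampler is a random-walk scheme: R-hat < 1.01 typically needs the
  default `sweeps = 10`; very short runs will warn.
- Self-consistency of agent thresholds is exact only up to the discreteness
  of simulated sessions (residuals up to ~0.05 apples at the default
  environment; larger in deliberately tiny test environments).
- The best-threshold search optimizes apples per second without subjective
  effort costs, matching the published environment-level benchmark, not any
  participant's subjective optimum.
- `T` uses the configured harvest duration as the harvest-time constant; if
  a real dataset's timing differs, set it in `foraging_config()` before
  fitting.
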