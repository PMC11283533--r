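---
title: "Methods: the assay-guided CLL treatment-sequencing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the assay-guided CLL treatment-sequencing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllcea)
```

# Overview

`cllcea` evaluates whether an NGS assay that stratifies newly treated CLL
patients into high- and low-risk groups — and sequences treatment
accordingly — is cost-effective against a standard of care in which every
patient starts the high-risk sequence. The engine is a discrete-time Markov
cohort model: occupancy fractions of mutually exclusive health states are
propagated through one row-stochastic transition matrix per monthly cycle
over a 10-year horizon (120 cycles), accruing discounted costs and
quality-adjusted life-years.

Three pathways are built from five regimens:

| pathway      | line 1                            | line 2                  | line 3 |
|--------------|-----------------------------------|-------------------------|--------|
| high-risk    | acalabrutinib (indefinite)        | venetoclax + rituximab (24 cycles) | idelalisib + rituximab |
| low-risk     | venetoclax + obinutuzumab (12 cycles) | acalabrutinib (indefinite) | idelalisib + rituximab |
| comparator   | identical to the high-risk pathway, no assay |  |  |

The intervention arm's outcomes are the prevalence-weighted mix of the two
pathways plus the assay cost (`mix_by_assay()`); the base case assumes a
perfectly accurate assay, so no misclassification pathways exist, and the
comparator is bitwise identical to the high-risk pathway without the assay.

# State space and transitions

`expand_states()` generates, per line $\ell$: `on_treatment_l`,
`ae_minor_l`, `ae_major_l`, and `treatment_free_l` for fixed-duration
regimens; shared across lines: `progression_post_3l` (relapse after third
line) and absorbing `death`. Utilities are annual-equivalent weights:
on-treatment 0.78/0.71/0.65 by line, minor AE 0.73, major AE 0.69,
treatment-free interval 0.91, relapse 0.68, death 0.

Per cycle, each on-treatment state faces competing events:

* **death** at the line's per-cycle overall-survival event probability,
* **progression** at the progression-free-survival event probability net of
  death (floored at zero), moving to the next line's on-treatment state, or
  to the relapse state after line 3,
* **minor adverse event**: a one-cycle excursion (utility 0.73, AE cost)
  returning to the same line,
* **major adverse event**: a one-cycle state (utility 0.69, AE cost), then
  treatment discontinuation — advance to the next line.

The residual probability stays on treatment, except that once a
fixed-duration regimen's duration has elapsed it flows into the line's
treatment-free state, where the line's progression clock keeps running but
drug cost stops. Any row summing above one (e.g. absurd AE inputs colliding
with a late-horizon hazard spike) is rejected with the offending cycle
named rather than renormalized silently.

## Time semantics (clock-forward)

All hazards — every line's PFS and OS, and fixed-duration completion — are
indexed by *model time*, not time-in-state. This is the standard
simplification when transition probabilities come from digitized trial
curves and the state space is not expanded into tunnel states (which we
deliberately avoid; patient-level or semi-Markov tracking is out of scope).
Two consequences are worth knowing:

* a later line's curve is read at the model clock, so a cohort reaching
  second line late faces that curve's late-time (conditional) hazard — later
  lines are effectively shortened;
* a fixed-duration line entered after model time already exceeds its
  duration contributes one on-treatment cycle (one cycle of drug cost)
  before the treatment-free interval.

The treatment-free interval keeps the completed line's PFS clock running
(progression risk persists); resetting the clock at completion would
require a tunnel expansion and is not implemented.

## Discounting and accrual

The discount factor at cycle $t$ is $(1+r)^{-t/12}$ with $r = 0.015$ per
year — an annual discrete rate with fractional monthly exponents, matching
Canadian guidance, not continuous compounding. QALYs accrue as occupancy
$\times$ utility $\times \Delta/12$ per cycle using start-of-cycle
occupancy; a half-cycle correction (averaging start and end occupancy) is
available as a config flag but is **off** in the reference case, since the
source analysis does not state one. The assay cost is applied once at cycle
0, undiscounted; general one-time costs are discounted at their cycle's
factor. Both choices are recorded in run manifests.

# Survival extrapolation

Digitized Kaplan–Meier coordinates (time in months, survival fraction) are
fitted with $S(t) = \exp(-(t/\lambda)^k)$ via ordinary least squares on
$\ln(-\ln S) = k\,\ln t - k\,\ln\lambda$. The choice is deliberate:
deterministic, desk-scale, reproducible, and it needs nothing but the curve
coordinates (no at-risk tables, no pseudo-individual-patient
reconstruction). Points with survival exactly 0 or 1 (or time 0) are
uninformative on the complementary log-log scale and are dropped with a
warning; at least three usable points are required. The exponential family
constrains $k = 1$ and estimates $\ln\lambda$ as the mean of
$\ln t - \ln(-\ln S)$.

The regression's coefficient covariance is propagated to
$(\ln k, \ln\lambda)$ by the delta method and stored with the fit — this is
what the PSA perturbs. Fits are converted to time-dependent per-cycle event
probabilities $p_i = 1 - S((i{+}1)\Delta)/S(i\Delta)$, whose cumulative
product reproduces $S$ exactly; death takes the OS event probability and
progression the PFS probability net of death.

Known numerical behaviour: the complementary log-log transform inflates the
noise of late, low-survival points, so the OLS fit and a sum-of-squared-
survival-error minimizer differ somewhat on noisy digitized curves (the
test suite brackets the OLS fit against a brute-force grid-search oracle at
20% on the shape and 10% on the scale). On noise-free same-family input the
fit recovers the generating parameters to numerical precision.

# Probabilistic sensitivity analysis

Per draw, with everything keyed to `(seed, draw_index, attempt, stream)` so
runs are bitwise reproducible:

* **utilities**: beta distributions moment-matched to (mean, SD); e.g. mean
  0.78, SD 0.14 gives $\alpha \approx 6.05$, $\beta \approx 1.71$.
  Infeasible moments ($SD^2 \ge m(1-m)$) are rejected at load with the
  utility named. SD 0 degenerates to the mean.
* **costs**: uniform on $[0.75c, 1.25c]$ for drug costs, $[0.25c, 1.75c]$
  for the assay — "±25% / ±75% variability" read as uniform bounds because
  no distribution is stated in the source; a gamma alternative was
  considered and rejected as an extra unstated assumption.
* **survival**: $(\ln k, \ln\lambda)$ drawn multivariate-normal around the
  fitted values with the fit covariance.

Common draws across arms is the default (standard practice: both arms see
identical parameters, so all incremental variance is structural).
An independent-sampling mode exists because one published scenario row
(100% high-risk with a *negative* incremental cost) is only explicable if
the arms were sampled independently; the mode used is echoed in the output
metadata. Draws producing an invalid schedule are rejected, logged and
resampled, capped at $10\times$ the iteration count.

Summaries report means and 95% intervals computed as mean $\pm 1.96\times$
sample SD — the source's stated formula, which describes the sampled
distribution rather than the standard error of the mean; the convention is
recorded in the summary object. The headline ICER is the ratio of mean
increments $\bar{\Delta C}/\bar{\Delta E}$ (not the mean of per-draw
ratios), the only convention consistent with the source's own worked
numbers. Its published ICER confidence interval is not reconstructible from
its $\Delta C$ and $\Delta E$ intervals under any standard formula, so the
package reports the ratio-of-means ICER plus mean±1.96·SD intervals for
$\Delta C$, $\Delta E$ and NMB, and leaves the discrepancy documented
rather than resolved.

# CEA statistics

* `icer()` returns $\Delta C/\Delta E$, or a dominance label
  (`"dominant"`/`"dominated"`), or `"undefined (dE ~ 0)"` when
  $|\Delta E| < 10^{-9}$ QALYs.
* `nmb()` is $\Delta E \times \lambda - \Delta C$ at $\lambda = 50{,}000$
  CAD/QALY by default.
* `ceac()` is the fraction of draws with $\lambda\Delta E - \Delta C > 0$
  on a grid (default 0–150,000 by 1,000); a draw with $\Delta E = 0$ counts
  as cost-effective iff $\Delta C < 0$, which is exactly the NMB rule, so
  CEAC membership, NMB sign and CE-plane position are mutually consistent
  by construction (and asserted per-draw in the tests).
* `ce_plane_quadrants()` assigns axis ties to the non-positive side; the
  SE quadrant ($\Delta E > 0$, $\Delta C \le 0$) is the dominant share.
* `scenario_sweep()` varies the assay cost or the high-risk prevalence. In
  deterministic mode the pathways are evaluated once and re-mixed per value
  — the assay cost enters $\Delta C$ additively, so
  $ICER(c) - ICER(0) = c/\Delta E$ exactly, and at prevalence 1 the arms
  coincide and $\Delta C$ equals the assay cost exactly. In PSA mode one
  set of draws is re-mixed across scenario values, keeping parameter
  uncertainty common across the sweep.

# The synthetic trial generator

No trial data ship with the package. `make_fixture_bundle()` simulates,
per regimen and endpoint: Weibull event times by inverse CDF on seeded
uniforms; censoring at the earlier of an exponential dropout time (0.005
per month) and an administrative cut-off (48/40/36 months by line);
Kaplan–Meier product-limit estimation; and digitization on a monthly grid
with Gaussian error (SD 0.01 survival units — plausible for manual plot
extraction), clamped to $[0,1]$ and re-monotonized by running minimum.

The generating parameters (`cll_synthetic_truth()`) encode the qualitative
structure the analysis assumes, chosen once:

* within each pathway, median PFS orders first > second > third line
  (each later line gives shorter remission);
* the low-risk pathway's first line is genuinely superior (PFS median ~31
  vs ~14 months; OS scale 90 vs 60), the premise of risk stratification —
  with these values the noise-free model gives $\Delta E \approx +0.64$
  QALYs and $\Delta C \approx +17{,}300$, i.e. the north-east quadrant at
  an ICER around $27,000/QALY, the reference analysis's qualitative
  pattern;
* 200 subjects per curve, in the range of the underlying phase-III trial
  arms.

What the generator does **not** emulate: the actual published trial curves
(medians and magnitudes are synthetic); within-subject correlation between
PFS and OS (endpoints are simulated independently); informative censoring;
at-risk-table-guided digitization. Passing tests therefore demonstrate that
the pipeline's machinery is correct and stable under realistic noise — not
that the shipped numbers estimate any real-world ICER.

# Numerical choices

* Row-stochasticity enforced at $10^{-12}$; absorbing rows must be exact
  identity; occupancy conservation asserted at $10^{-12}$ per cycle.
* $\Delta E$ treated as zero below $10^{-9}$ QALYs when forming ICERs.
* Survival points at exactly 0/1 dropped from fits (log-undefined); fewer
  than 3 usable points is an error, not a guess.
* PSA rejection resampling capped at $10\times n$; rejected counts
  reported.
* Monte-Carlo oracle checks: a cohort trace is validated against a
  first-order microsimulation (per-state multinomial counts, the sufficient
  statistic of individual-level simulation). Marginally each cell is
  binomial, so with ~1,400 state×cycle cells a few $|Z|>3$ exceedances are
  expected *from an exact trace*; the equivalence check is therefore
  multiplicity-aware — at least 99.5% of well-populated cells within 3 SE,
  all within 5 SE, sparse cells (expected count < 5) within a 30-count
  bound.
* Test problem sizes are the package's own choices for a desk-scale,
  deterministic suite: 200,000-subject microsimulations, 200-replicate
  round-trip recovery at 500 subjects per trial, 1,000-draw PSA runs.

# Limitations

Beyond the generator's simplifications above: the clock-forward time
semantics shorten later lines relative to a semi-Markov model; adverse
events occupy exactly one cycle because the source states no dwell time;
AE probabilities and management costs are synthetic configuration defaults
(the source cites literature values without printing them);
misclassification (assay sensitivity/specificity below 1) is structurally
supported but rejected at runtime unless misclassified-pathway outcomes are
supplied; and no budget-impact, equity weighting or multi-strategy frontier
analysis is attempted.
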