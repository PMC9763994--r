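---
title: "Predictive probability monitoring for randomized biomarker-guided phase II trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive probability monitoring for randomized biomarker-guided phase II trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdesigns)
```

## The problem

Early-phase oncology trials of biomarker-targeted agents are often run as
single-arm studies judged against a historical control rate.  When the
biomarker is prognostic, the historical population average can badly
misrepresent the control response rate inside the biomarker-defined
subgroup, and an apparently promising phase II result evaporates in the
randomized phase III.  `ppdesigns` implements randomized alternatives:
three phase II topologies in which each biomarker-specific treatment
cohort is compared against a concurrent randomized control, with Bayesian
predictive probability monitoring so that inactive cohorts stop early.

The motivating setting has three biomarker subgroups of equal prevalence
(labelled IC0, IC1 and IC2/3 after PD-L1 immune-cell expression strata), a
10% control response rate, and a binary response endpoint.  Under the
predictive-biomarker alternative the treatment response rates are 10%, 20%
and 30% in the three subgroups; a homogeneous 30% alternative is also
provided (`scenario_homogeneous()`).

## Model and monitoring rule

Each arm's response count is binomial with rate $p$, with a conjugate
$\mathrm{Beta}(a_0, b_0)$ prior, so after $x$ responses in $n$ patients
the posterior is $\mathrm{Beta}(a_0 + x,\, b_0 + n - x)$.  The default
prior is Jeffreys' $\mathrm{Beta}(0.5, 0.5)$, the information of roughly
one patient.  Efficacy is judged by the two-sample posterior comparison

$$\Pr(p_T > p_C \mid \text{data}) > \theta,$$

evaluated by adaptive quadrature to an absolute tolerance of $10^{-8}$
(half-integer posterior shapes rule out the integer-shape closed form).

At an interim look with $n^*_T$ and $n^*_C$ patients still to enroll, the
two-sample posterior predictive probability (PPP) of end-of-trial success
is computed by exact joint enumeration: future response totals in the two
arms are independent beta-binomials, so

$$\mathrm{PPP} \;=\; \sum_{y_T=0}^{n^*_T} \sum_{y_C=0}^{n^*_C}
  \Pr(y_T \mid x_T) \Pr(y_C \mid x_C)\,
  \mathbf{1}\{\Pr(p_T > p_C \mid \text{completed data}) > \theta\}.$$

Enrollment of a comparison stops for futility when
$\mathrm{PPP} < \theta^*$.  With no patients remaining the PPP degenerates
to the 0/1 indicator of the posterior decision, which is exactly the final
analysis rule.  Enumeration is exact and cheap (at most
$51 \times 51$ terms per state in the case study), so no Monte Carlo
approximation is used inside the monitoring rule itself.

## The three topologies

* **Pooled control arm** (`design_config("pooled", ...)`): 3:1
  randomization to treatment versus control; only treated patients are
  biomarker-typed, so one biomarker-unselected control arm (max 50) serves
  all three treatment cohorts (max 50 each; trial max 200).  The control
  arm keeps enrolling while at least one treatment cohort is open.
* **Stratified control arm** (`"stratified"`): all patients are typed and
  randomized 1:1 within subgroup (max $6 \times 50 = 300$); the two arms
  of a subgroup stop together, so control and treatment enrollment are
  equal by construction.
* **Two-stage enrichment** (`"enrichment"`): stage 1 is the pooled design.
  At its end, the subgroup with the highest last-computed PPP advances to
  stage 2 provided it did not stop for futility and its PPP exceeds a
  lower bound calibrated under the null; otherwise the trial stops.  Stage
  2 enrolls 100 additional patients of the selected subgroup 1:1, carries
  the stage-1 treatment data forward (treatment maximum $50 + 50$ against
  a fresh control maximum of 50), and continues futility monitoring.
  Stage-1 pooled control data are not reused at stage 2: that control arm
  is a biomarker-unselected mixture, while the stage-2 comparison is
  within the selected subgroup.

## Simulation protocol

Responses are generated in blocks of `look_interval` (default 10) patients
per arm, and every open comparison is examined after each block, i.e. at
per-arm 10, 20, 30 and 40 in the case study; the evaluation at 50 is the
final analysis.  This block-accrual convention realizes the randomization
ratios through the fixed arm maxima rather than by patient-level
randomization, which matches how such trials are planned and keeps each
state exactly enumerable.  One master seed spawns every random stream
(null replicates, alternative replicates, bound-calibration replicates,
stage-2 patients), so a configuration plus a seed reproduces every number
exactly.

Two implementation choices make grid calibration fast without changing any
result: (i) posterior-comparison probabilities and predictive weights are
cached per completed-data state, since calibration revisits identical
states millions of times; (ii) within `estimate_oc()` the same simulated
response streams are reused across all threshold combinations (common
random numbers), so cells differ only through the thresholds applied to
identical trajectories.  At the case-study scale the full
$14 \times 4$ grid for one design runs in a few seconds on one core, and
the packaged test suite (including three 1000-replicate acceptance
simulations and the full grids) in well under a minute.

## Calibration and optimal-efficiency selection

`estimate_oc()` simulates 1000 replicates under the null and the
alternative and reports, per cell: the calibration type I error (IC0
subgroup declared positive under the null), the calibration power (IC2/3
positive under the alternative), per-subgroup detail, and average sample
sizes.  `filter_acceptable()` keeps cells with type I error in
$[0.05, 0.1]$ and power at least $0.8$.  `select_optimal_efficiency()`
then minimizes the Euclidean distance to the efficiency ideal — the
smallest average total N under the null and the largest under the
alternative attained within the acceptable set — with a deterministic tie
break (higher power, lower type I error, lower $\theta$, lower
$\theta^*$) so the selection is invariant to row order.  The corners are
computed over the constraint-satisfying set; computing them over the full
grid is a defensible alternative and can shift the winner among near-tied
cells, a reminder that with 1000 replicates the distance ranking of
neighbouring cells is well within Monte Carlo noise and the selected cell
should be read as "one of the near-optimal designs", not a sharp optimum.

For the enrichment design the calibration metrics follow the stage-2
convention: type I error and power are proportions among the replicates
that advanced to stage 2 (the stage-2 calibration set is smaller than the
number of simulated trials); the proportions over all replicates are
reported alongside (`stage2_*_all` columns).  Cells that never advance
carry `NA` conditional operating characteristics and are excluded by the
acceptability filter.

## Numerical choices and degenerate inputs

* **Quadrature orientation.** $\Pr(p_1 > p_2)$ integrates the CDF of one
  beta against the density of the other; the density role is given to the
  distribution whose smallest shape is larger, which keeps the integrand
  well behaved when an improper-prior posterior concentrates at 0 or 1.
* **Improper priors.** $\mathrm{Beta}(0,0)$ is admitted for sensitivity
  analysis.  Any completed-data state that would leave a zero posterior
  shape (no responses, or no failures, in an arm) is evaluated with the
  shape replaced by $10^{-6}$, and the substitution is announced once per
  decision surface.  `update_posterior()` itself refuses an improper
  posterior so that interactive misuse is caught early.
* **Stage-1 selection metric.** For a subgroup stopped at an interim look
  the last computed PPP (a value below $\theta^*$) enters the selection
  maximum; for a subgroup reaching full enrollment the end-of-trial PPP is
  the 0/1 posterior-decision indicator.  Stopped subgroups are ineligible
  to advance regardless of rank.  A consequence worth knowing: completed
  subgroups contribute only 0 or 1, so for any advancement bound strictly
  inside $(0,1)$ the bound itself rarely binds and stage-1 advancement is
  essentially "some subgroup completed positive".  Ties between two
  positive subgroups are broken by the larger final posterior probability.
* **Bound quantile.** The stage-1 bound is the 80th percentile (the
  default quantile type of `stats::quantile()`) of the per-replicate
  maximum PPP across subgroups under the global null.
* **Zero-PPP states.** Even with $\theta^* \to 0$ a comparison stops in
  states from which no completion can satisfy the posterior decision
  (PPP exactly 0); the extreme-threshold tests check exactly this.

## What the generator emulates — and what it does not

The generator reproduces the trial mechanics that drive the operating
characteristics: binomial responses at fixed true rates, block accrual,
subgroup prevalence, and the monitoring rule applied at the stated looks.
It does not model accrual-time variation, patient dropout or missing
biomarker results, response-assessment delay between enrollment and
interim analysis, or drift in the control rate over calendar time.
Passing tests therefore demonstrate that the decision rules have the
claimed frequency properties under the stated sampling model, not that a
real trial with delayed response assessment would stop at exactly these
enrollment counts; in practice the decision tables would be applied at
whatever counts are observed when a look occurs.

## Decision tables for trial conduct

`build_decision_table()` tabulates, for each look and each possible
control response count, the minimum treatment response count that
continues enrollment, plus the final efficacy boundary — so a trial can be
run from a printed table with no mid-trial computation.  The tables are
exact restatements of the simulator's rule and the test suite checks their
agreement state by state.

## Known limitations

* Binary endpoints only; time-to-event monitoring is out of scope.
* The three topologies are fixed; variants such as dropping the stage-1
  control arm of the enrichment design are not implemented.
* No multiplicity adjustment is applied across the three subgroup
  comparisons, mirroring the case-study convention; users who need strong
  familywise control should calibrate thresholds accordingly.
* Operating-characteristic estimates carry Monte Carlo error of roughly
  $\pm 0.013$ (standard error) on proportions near 0.8 at 1000
  replicates; grid selection among near-tied cells inherits that noise.

## A compact example

```{r example, eval = FALSE}
cfg <- design_config("pooled", theta = 0.9, theta_star = 0.1, n_sim = 1000)
sim <- simulate_design(cfg, scenario_alternative(), seed = 42)
print(sim)

oc <- estimate_oc("pooled", n_sim = 1000, seed = 1)
best <- select_optimal_efficiency(filter_acceptable(oc))
best[best$optimal, c("theta", "theta_star", "type1", "power",
                     "avg_n_null", "avg_n_alt")]
```
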