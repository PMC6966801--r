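---
title: "Conditional power, futility stopping, and auditing truncated trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional power, futility stopping, and auditing truncated trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpaudit)
```

## The model

`cpaudit` works on the information-time scale. For a two-arm comparison with
effect estimate $\hat\theta_k$ at the $k$-th interim analysis, the
statistical information is $I_k = \mathrm{SE}(\hat\theta_k)^{-2}$ and
information time is $t_k = I_k / I_K$, with $I_K$ the planned total. The
score process $S(t) = \hat\theta(t)\, I(t)$ is modelled as Brownian motion
with drift: increments over $(t, t')$ are independent
$N(\theta I_K (t'-t),\; I_K (t'-t))$. This is the standard large-sample
approximation for group-sequential monitoring; it treats the interim
statistic $Z_k = S(t_k)/\sqrt{I_K t_k}$ as exactly normal and is the model
under which the closed-form conditional power holds.

Conditional power at look $k$ under a hypothesised future effect $\theta$
is the probability that the final test rejects, given $Z_k$:

$$
CP_k(\theta) = 1 - \Phi\!\left(
  \frac{c - Z_k\sqrt{t_k} - \theta\sqrt{I_K}(1-t_k)}{\sqrt{1-t_k}}\right),
$$

one-sided, with the two-sided version adding the mirror-image term
$\Phi\!\left((-c - Z_k\sqrt{t_k} - \theta\sqrt{I_K}(1-t_k))/\sqrt{1-t_k}\right)$.

Assumptions worth stating explicitly:

* **Normality of increments.** Exact for large samples on risk-difference,
  mean-difference and log-hazard-ratio scales; small trials with very
  discrete outcomes will deviate.
* **A single, fixed final test.** No alpha-spending adjustment is made for
  the interim looks themselves; this mirrors how futility (as opposed to
  benefit) monitoring is usually analysed, since stopping for futility
  cannot inflate type-I error.
* **Benefit-positive orientation.** All effects and statistics are signed
  so that positive favours the experimental arm. The one-sided formula is
  direction-specific, so converters must orient inputs before use.

### The critical value for two-sided tests

The critical value is $c = \Phi^{-1}(1-\alpha)$ for one-sided tests and
$c = \Phi^{-1}(1-\alpha/2)$ for two-sided tests. The $\alpha/2$ convention
was an open choice: some presentations of the two-sided CP formula reuse the
one-sided quantile. We use $\alpha/2$ so that the two-sided CP at zero
information under the null equals $\alpha$ exactly — the unconditional
rejection probability — which makes the formula internally consistent.
Every `cp_result` records which convention produced it.

### Hypotheses about future data

Four conventions for $\theta$ are supported: `current_trend`
($\theta = \hat\theta_k$), `design` ($\theta = \theta_d$ from the
protocol), `upper_cl`
($\theta = \hat\theta_k + \Phi^{-1}((1+\gamma)/2)\,\mathrm{SE}$, the upper
limit of a two-sided $\gamma$ confidence interval), and `null`
($\theta = 0$). Because CP is strictly increasing in $\theta$ for one-sided
tests, the design hypothesis always dominates the current trend whenever
$\theta_d > \hat\theta_k$ — the quantitative reason the stop/continue
decision hinges on which future one believes. For **two-sided** tests this
monotonicity fails over negative estimates (the harm-direction tail starts
contributing), so the dominance property is only asserted for
benefit-direction interims.

## Tunable parameters

* `alpha` (type-I error, default 0.05): the design's planned level, in
  (0, 0.5].
* `threshold` (default **0.15**): the futility cut-off on CP. Conventional
  practice puts it in 0.10–0.15 under the design hypothesis; 0.15 is the
  value used throughout and is overridable everywhere it appears. The
  classification is *strict* (`cp < threshold`), so a trial exactly at the
  threshold is not futile.
* `effect` ($\theta_d$): on the natural analysis scale — the same scale as
  its standard error, log scale for ratio measures — so that
  $\theta\sqrt{I_K}$ is dimensionless.
* `total_information`: explicit $I_K$ always wins; otherwise it is derived
  as $((c + \Phi^{-1}(\text{power}))/|\theta_d|)^2$. It is never derived
  from the planned sample size alone, because no variance model is
  available for a bare $n$.

## Converting reported summaries

Trial reports rarely give $Z_k$ and $t_k$ directly. The converters fix one
standard variance formula per outcome type and tag every output with a
`method` string so audits are traceable:

* risk difference: unpooled Wald,
  $\mathrm{SE} = \sqrt{p_1(1-p_1)/n_1 + p_0(1-p_0)/n_0}$;
* log odds ratio: Woolf, $\sqrt{1/a + 1/b + 1/c + 1/d}$, with an opt-in
  $+0.5$ continuity correction (default off; a zero cell without it is an
  error naming the cell);
* mean difference: two-sample Wald;
* log hazard ratio: the reported SE when present, else the 1:1-allocation
  approximation $I \approx d/4$ from the event count, flagged as
  approximate (a test cross-checks it against a Cox fit near the null);
* exact p-values: inverted through the normal quantile, signed by the
  reported direction. P-values given only as bounds ("<0.001", "NS") are
  refused with an insufficient-information error — imputing them would
  manufacture precision the report does not contain.

## The audit pipeline

`audit_trial()` resolves each quantity through a fixed preference order
(statistic: `z_value`, then `estimate`/`se`, then exact `p_value`, then
per-arm summaries; information fraction: `info_fraction`, then
`interim_n/planned_total_n`, then $\mathrm{SE}^{-2}/I_K$; total
information: explicit, then derived) and computes CP under the
current-trend and design hypotheses, each independently allowed to fail.
Verdicts are `computed`, `reported_only` (an author-reported CP retained
verbatim — it is never back-solved, because the reporting trial's
convention is usually unstated), or `insufficient` with a machine-readable
reason. Where both a computed and a reported value exist, both are emitted;
the computed one drives the futility flag, since a recomputation with a
stated convention is more defensible for a reusable audit tool.

Degenerate and awkward inputs:

* an interim **at or beyond full information** raises a distinct error
  class and audits as a flagged failure — CP is undefined there and is
  never silently clamped (surveys do meet such trials);
* information fractions in $(1, 100]$ are read as percentages, logged under
  `assumptions`;
* missing or "unclear" sidedness falls back to a configurable default
  (two-sided, the majority convention), also logged;
* every other inconsistency (e.g. `z` $\neq$ `estimate/se` beyond relative
  tolerance $10^{-8}$) is a domain error collected as a failure reason.

CP distributions are summarised in the conventional survey bins
$[0, 0.15)$, $[0.15, 0.30)$, $[0.30, 0.50)$, $[0.50, 1]$ — left-closed so
that "less than 15%" is literal, last bin closed. Reported-only values are
binned under the current-trend hypothesis, the treatment surveys apply when
authors do not state their assumption. Conservation (statuses sum to the
number of trials, bins sum to the number of binned CPs) is asserted on
every summary.

## The synthetic registry

`generate_registry()` emulates the marginal structure of a surveyed cohort
of 52 trials stopped for futility: outcome mix 33/10/8 over
binary/continuous/time-to-event, sponsors 21 industry / 31 non-industry,
sidedness 14/33/5 (one/two/unclear), planned power drawn from
{0.75, 0.80, 0.90} with weights 1/32/15, planned total sample size
lognormal with median 209 (log-sd 1.1, chosen to match the surveyed
inter-quartile width of roughly 133–586 on the log scale; a lognormal
cannot match both asymmetric quartiles exactly), and interim timing
concentrated near half information (bin weights 11/20/12/6 from under 40%
to over 80%). About 16/52 of rows carry only a bounded p-value and audit as
insufficient; 11/52 carry a rounded author-reported CP and nothing
computable. The true effect defaults to **half the design effect**,
reflecting the well-documented tendency of realised effects in stopped
trials to run well below their targets; the ratio is configurable.

What the generator does *not* emulate: joint dependencies between columns
(sponsor × outcome type etc. are independent), non-normal small-sample
behaviour, informative missingness, and any benefit-stopping boundary. A
green audit of synthetic registries therefore demonstrates the pipeline's
correctness and calibration under the stated marginals, not fidelity to any
particular real cohort.

## The simulator and the bias properties

`simulate_trials()` draws exact-normal score increments between looks, so
it is simultaneously a Monte-Carlo oracle for the closed form (the two are
required to agree within three binomial standard errors over a fuzz grid)
and a demonstration of what futility rules do to estimation. The final
estimate of a stopped trial is its interim estimate $S_k/I_k$, with no
bias adjustment — mirroring how truncated trials actually report. The
current-trend rule inside the simulator recomputes the running estimate at
every look. One RNG stream per trial is derived from the master seed, so
results cannot depend on execution order; the single-trial and batch
entry points share the same core and agree exactly.

At $\theta_{true} = \theta_d/2$ with one look at half information and a
0.15 current-trend threshold, the simulated strata reproduce the three
directional claims: stopped trials under-estimate (bias about $-0.13$ at
$\theta_{true} = 0.15$), completed trials over-estimate (about $+0.04$),
and the overall mean is biased downward (about $-0.025$); with the rule
disabled the overall bias is statistically zero. The `significant` flag is
`NA` for stopped trials, where the final test never happens.

## Numerical choices

* All normal CDF/quantile evaluations are double precision (`pnorm`,
  `qnorm`); no series approximations are used.
* CP is clamped to $[0, 1]$ only against floating-point overshoot (guard
  $10^{-12}$); the formula itself cannot leave the interval.
* Consistency identities (`information = se^-2`,
  `z = estimate/se`) are enforced at relative tolerance $10^{-8}$.
* Monte-Carlo comparisons use binomial standard errors evaluated at the
  closed-form value, with a $1/n$ guard for near-degenerate probabilities.
* Test problem sizes: $10^5$ draws per point for oracle grids, $10^5$
  simulated trials for the bias strata, $10^4$ for stopping probabilities —
  sizes at which the Monte-Carlo error is far below every asserted effect
  while the whole suite runs in well under a minute.

## Known limitations

* Trinomial and other exotic outcome types are not supported by the
  converters (an explicit non-goal; such trials audit as insufficient
  unless a usable statistic is reported directly).
* No alpha-spending or repeated-confidence-interval machinery: the package
  audits futility decisions, it does not design stopping boundaries.
* No adjustment of post-stopping estimates; the simulator quantifies the
  bias, it does not correct it.
* The Brownian model ignores overrunning (patients accrued between the
  interim cut and the stop decision), which surveys show is common; an
  audited `info_fraction` reflects the analysed interim, not the final
  reported sample size.
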