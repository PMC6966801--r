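# cpaudit

Conditional-power auditing of randomised trials stopped early for futility.

Many randomised controlled trials include interim analyses with the option of
stopping for futility: if the accumulating data make a statistically
significant final result sufficiently unlikely, the trial is terminated
before its planned sample size. The standard quantitative basis for that
decision is **conditional power** (CP) — the probability of rejecting the
null at the planned completion, given the interim data and a hypothesised
true effect θ for the data not yet observed. Trials that stop this way
report their results anyway, and the stopping rule itself distorts
estimation: trials that stop under-estimate the treatment effect, trials
that carry a rule but complete over-estimate it, and the overall expectation
is biased downward.

`cpaudit` is aimed at trial statisticians, DSMB members and
meta-epidemiologists who want to (i) compute CP from whatever a trial report
actually provides, (ii) audit a whole registry of stopped trials the way a
systematic survey would, and (iii) quantify, by simulation, what a futility
rule does to effect estimation.

## The model

A two-arm trial is represented by its score process on information time
t = I_k / I_K, where I = SE(θ̂)⁻² is the statistical information and I_K the
planned total. The interim statistic is Z_k = S(t_k)/√(I_k). One-sided
conditional power at look k under a hypothesised future effect θ is

    CP_k(θ) = 1 − Φ( (c − Z_k √t_k − θ √I_K (1 − t_k)) / √(1 − t_k) )

and the two-sided version adds the symmetric lower-tail term
Φ((−c − Z_k√t_k − θ√I_K(1−t_k))/√(1−t_k)). The critical value is
c = Φ⁻¹(1−α) one-sided and Φ⁻¹(1−α/2) two-sided, so the null rejection
probability is exactly α either way. Four conventions for θ are supported:
the **current trend** (θ = θ̂_k), the **design hypothesis** (θ = θ_d from
the protocol), the optimistic **upper confidence limit**, and the **null**.
A trial is classified futile when CP falls strictly below a threshold
(default 0.15).

## Worked example

A trial designed one-sided at α = 0.025 with 90% power to detect θ_d = 0.3
looks at its data at half information and sees θ̂ = 0.13 (SE 0.131):

```r
library(cpaudit)

design  <- design_spec(alpha = 0.025, sidedness = "one", power = 0.9, effect = 0.3)
interim <- interim_state(estimate = 0.13, se = 0.131, info_fraction = 0.5)

conditional_power(interim, design, "current_trend")
#> <cp_result> CP = 0.2159 under current_trend hypothesis (theta = 0.13)
#>   t_k = 0.500, one-sided c = 1.9600, futile at 0.15: FALSE

conditional_power(interim, design, "design")
#> <cp_result> CP = 0.6959 under design hypothesis (theta = 0.3)
#>   t_k = 0.500, one-sided c = 1.9600, futile at 0.15: FALSE
```

If the disappointing current trend is believed, only a 22% chance of final
significance remains; if the protocol's design effect is still credible, CP
is 70% and stopping would be hard to defend — the decision hinges on the
future-data assumption, which is exactly why audits record both.

Registry-scale use follows the same grammar, with data frames in and
tibbles out:

```r
registry <- generate_registry(n_trials = 52, seed = 2026)   # synthetic survey
audits   <- audit_registry(registry, threshold = 0.15)
summ     <- summarize_survey(audits, registry)
summ
#> <survey_summary> 52 trials
#> Audit status:
#>   computed       34
#>   reported_only  6
#>   insufficient   12
#> Conditional-power bins:
#>     hypothesis <15% 15-30% 30-50% >=50%
#>  current_trend   16      4      6    14
#>         design    5      3      5    21
autoplot(summ)                    # binned CP distribution, per hypothesis
```

Each trial is audited as `computed` (CP recomputed from its report, under
both hypotheses), `reported_only` (the authors' CP retained verbatim because
nothing is computable), or `insufficient` (with a machine-readable reason —
e.g. a p-value reported only as "<0.001" is refused, never imputed). Real
registries are read with `read_registry("trials.csv")`; the column schema
ships in `inst/extdata/registry_schema.csv` and a three-row example in
`inst/extdata/example_registry.csv`.

The simulator provides the Monte-Carlo oracle for the closed form and makes
the estimation-bias claims checkable:

```r
cfg  <- sim_config(design, theta_true = 0.15, look_fractions = 0.5,
                   hypothesis = "current_trend", threshold = 0.15,
                   n_sim = 1e5, seed = 1)
bias_summary(simulate_trials(cfg), theta_true = 0.15)
```

A thin command-line interface over the same functions lives at
`inst/cli/cpaudit.R` (subcommands `compute-cp`, `audit`,
`generate-registry`, `simulate`).

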