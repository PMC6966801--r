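column,type,domain,description
trial_id,character,unique and required,Unique trial identifier
outcome_kind,character,"binary|continuous|time_to_event|other",Primary outcome type
measure,character,"risk_difference|log_odds_ratio|mean_difference|log_hazard_ratio",Effect measure of the interim estimate
sponsor,character,"industry|non_industry|unknown",Trial sponsor class
dsmb,logical,,Data safety and monitoring board present
decision_maker,character,free text,Who made the decision to stop
alpha,numeric,"(0, 0.5]",Planned type-I error rate
sidedness,character,"one|two|unclear",Sidedness of the planned significance test
planned_power,numeric,"(0, 1)",Planned power
design_effect,numeric,nonzero,"Design effect size, benefit-positive, natural analysis scale"
design_effect_scale,character,"natural|log_ratio",Scale of design_effect (log scale for ratio measures)
planned_total_n,integer,positive,Planned total sample size (descriptive only)
total_information,numeric,positive,Explicit total information I_K; takes precedence over the derived value
n_looks_planned,integer,nonnegative,Number of planned interim analyses
n_looks_actual,integer,nonnegative,Number of interim analyses actually performed
info_fraction,numeric,"(0, 1); values in (1, 100] read as percent",Information fraction at the last interim analysis
interim_n,integer,positive,Sample size at the last interim analysis
estimate,numeric,,"Interim effect estimate, benefit-positive"
se,numeric,positive,Standard error of the interim estimate
z_value,numeric,,"Interim test statistic, benefit-positive"
p_value,numeric,"(0, 1)",Exact interim p-value
p_is_bound,logical,,TRUE when the p-value is only an inequality (e.g. reported as <0.001)
reported_cp,numeric,"[0, 1]",Conditional power reported by the trial's authors (retained verbatim)
reported_cp_hypothesis,character,"current_trend|design|upper_cl|null",Hypothesis the authors stated for their reported value (usually missing)
data_collection_continued,logical,,Data collection continued after the last interim analysis
events_treat,integer,nonnegative,Optional per-arm summary: events in treatment arm
n_treat,integer,positive,Optional per-arm summary: treatment arm size
events_ctrl,integer,nonnegative,Optional per-arm summary: events in control arm
n_ctrl,integer,positive,Optional per-arm summary: control arm size
mean_treat,numeric,,Optional per-arm summary: treatment arm mean
sd_treat,numeric,positive,Optional per-arm summary: treatment arm SD
mean_ctrl,numeric,,Optional per-arm summary: control arm mean
sd_ctrl,numeric,positive,Optional per-arm summary: control arm SD
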