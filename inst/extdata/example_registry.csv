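trial_id,outcome_kind,measure,sponsor,alpha,sidedness,planned_power,design_effect,planned_total_n,info_fraction,estimate,se,z_value,p_value,p_is_bound,reported_cp,reported_cp_hypothesis
S01,binary,risk_difference,industry,0.05,two,0.8,0.3,200,0.5,0.06,0.065,,,FALSE,,
S02,continuous,mean_difference,non_industry,0.05,two,0.9,0.4,150,0.45,,,,,TRUE,0.54,
S03,time_to_event,log_hazard_ratio,non_industry,0.025,one,0.8,0.35,300,0.6,,,,0.001,TRUE,,
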