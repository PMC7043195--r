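contrast,rate_rule_pct,rate_reference_pct,printed_ratio,printed_nnt
itr_vs_observed_primary,51.7,44.5,1.16,13.9
itr_vs_observed_psych_hosp_or_change,54.0,46.4,1.16,NA
itr_vs_observed_psych_hosp_only,86.9,81.7,1.06,NA
itr_vs_observed_change_only,57.0,49.5,1.15,NA
observed_vs_uniform,44.5,41.3,NA,NA
observed_vs_proportional,44.5,43.5,NA,NA
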