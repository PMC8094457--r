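analysis,urethroplasty_cost,urethrotomy_cost,urethroplasty_qaly,urethrotomy_qaly
base_case_24m_post_rand,4869,2721,1.74,1.75
post_surgery,4963,3291,1.73,1.77
post_surgery_rescaled,4963,3291,1.42,1.58
imputed_24m_post_rand,4704,3371,1.73,1.76
intervention_and_reintervention,4332,2209,NA,NA
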