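# Illustrative default decision-model parameters (synthetic, non-canonical).
# Chosen to sit in the regime implied by the within-trial estimates: initial
# procedure costs near the observed arm means, a lower per-cycle recurrence
# probability after urethroplasty, and state utilities giving ~7.6 discounted
# QALYs over the decade for both strategies.
procedures:
  urethroplasty:
    procedure_cost: 4332.0
    p_recur: 0.048
  urethrotomy:
    procedure_cost: 2209.0
    p_recur: 0.067
p_death: 0.004
u_symptom_free: 0.930
u_symptomatic: 0.808
followup_cost: 78.0
recurrence_policy: observed_mix
p_switch: 0.55
recurrence_utility_decrement: 0.0
cycle_length: 0.5
horizon: 10
discount_rate_costs: 0.035
discount_rate_qalys: 0.035
half_cycle: false
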