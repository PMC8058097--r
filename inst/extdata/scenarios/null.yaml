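# No planted age effects anywhere; hypermutator rates equal across age.
cancer_type: "NULL-like"
gi_slope: 0
loh_slope: 0
wgd_logit_slope: 0
burden_log_slope: 0
ct_fraction_slope: 0
driver_or_per_year: 1
hypermutator_rate_young: 0.05
hypermutator_rate_old: 0.05
meth_age_slope: 0
coupling: 0
expr_age_slope: 0
arm_gain_or_per_year: 1
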