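# Glioma-like: driver mutation odds fall with age, no young hypermutator
# excess, instability still rises with age.
cancer_type: "LGG-like"
driver_or_per_year: 0.95
driver_intercept: 1.5
hypermutator_rate_young: 0.02
hypermutator_rate_old: 0.02
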