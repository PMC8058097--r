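# Endometrial-like study conditions: these are the generator defaults.
cancer_type: "UCEC-like"
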