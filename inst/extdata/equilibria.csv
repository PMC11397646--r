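compound_id,solvent,temperature_K,percent_beta,percent_alpha
121,DMSO-d6,298,47.1,52.9
38,pyridine-d5,298,86.7,13.3
48,DMSO-d6,298,86.0,
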