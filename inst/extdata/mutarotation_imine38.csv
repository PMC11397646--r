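compound_id,solvent,time_value,time_unit,percent_beta
38,pyridine-d5,0,h,85.9
38,pyridine-d5,1,h,85.9
38,pyridine-d5,8,h,86.0
38,pyridine-d5,1,d,85.3
38,pyridine-d5,3,d,84.5
38,pyridine-d5,5,d,87.9
38,pyridine-d5,7,d,86.7
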