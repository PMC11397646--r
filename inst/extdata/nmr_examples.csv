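species_id,j_h1_h2,one_bond_j_c1_h1,j_ch_eq_ch,j_ch_chn,optical_rotation_d,rotation_solvent,acetylated
108,3.3,165.5,,,,,FALSE
48,8.4,153.7,,,,,FALSE
45,7.7,,16.1,8.8,31.2,pyridine,FALSE
31,3.5,,,,154.0,pyridine,FALSE
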