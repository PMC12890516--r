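sample_id	group
control_r1	control
control_r2	control
control_r3	control
control_r4	control
disease_r1	disease
disease_r2	disease
disease_r3	disease
disease_r4	disease
treated_r1	treated
treated_r2	treated
treated_r3	treated
treated_r4	treated
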