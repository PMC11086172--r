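name,eps_r,sigma,eps_unc,sigma_unc,ref_freq_hz,source_table
skin,41,0.85,0,0,1e9,numerical
bone,18,0.40,0,0,1e9,numerical
CSF,68.2,2.30,0,0,1e9,numerical
white_matter,35.58,0.62,0,0,1e9,numerical
gray_matter,52.30,0.98,0,0,1e9,numerical
skin,41,0.53,2,0.05,1e9,physical
bone,12,0.20,1,0.07,1e9,physical
CSF,68,2.5,8,0.3,1e9,physical
brain,42,0.71,2,0.03,1e9,physical
blood,61,1.62,3,0.08,1e9,physical
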