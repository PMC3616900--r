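workflow	n_regulons	description
1	41	expansion and projection of regulons characterized in model lactic acid bacteria
2	14	projection of regulons characterized in external model Firmicutes (12 + 2 source organisms)
3	47	ab initio inference from conserved gene neighborhoods
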