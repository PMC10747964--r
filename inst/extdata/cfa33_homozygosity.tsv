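cohort	homozygous	not_homozygous
cases	3	20
controls	52	36
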