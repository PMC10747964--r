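case_id	subtype
L01	B-cell
L02	B-cell
L03	B-cell
L04	B-cell
L05	B-cell
L06	B-cell
L07	B-cell
L08	B-cell
L09	T-cell
L10	T-cell
L11	T-cell
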